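# Tetraspanin phenotype calling per cluster and per-sample summaries.

#' Call the tetraspanin phenotype of each cluster
#'
#' A channel is positive when strictly more than `threshold` of the
#' cluster's molecules in that channel lie within `radius_nm` of the
#' cluster centre (the single-particle positivity rule: more than 3
#' molecules within 150 nm).  The two channel booleans give the phenotype:
#' `CD81_only` (channel 1), `CD9_only` (channel 2), `double_positive`, or
#' `none`.
#'
#' @param cl an `"ev_clusters"` object.
#' @param threshold strict molecule-count threshold per channel (default 3).
#' @param radius_nm counting radius around the cluster centre (default 150).
#' @return data.frame `cluster_id, n_ch1_within, n_ch2_within, phenotype`
#'   with `phenotype` a factor with levels `CD81_only, CD9_only,
#'   double_positive, none`.
#' @export
call_phenotypes <- function(cl, threshold = 3L, radius_nm = 150) {
  stopifnot(inherits(cl, "ev_clusters"))
  check_num(threshold, "threshold", lower = 0)
  check_num(radius_nm, "radius_nm", lower = 0, strict = TRUE)
  mols <- cl$molecules
  out <- cl$clusters[, "cluster_id", drop = FALSE]
  n1 <- integer(nrow(out)); n2 <- integer(nrow(out))
  for (i in seq_len(nrow(out))) {
    cid <- out$cluster_id[i]
    mi <- which(!is.na(mols$cluster_id) & mols$cluster_id == cid)
    d2 <- (mols$x[mi] - cl$clusters$x[i])^2 + (mols$y[mi] - cl$clusters$y[i])^2
    near <- d2 <= radius_nm^2
    n1[i] <- sum(near & mols$channel[mi] == 1L)
    n2[i] <- sum(near & mols$channel[mi] == 2L)
  }
  pos1 <- n1 > threshold
  pos2 <- n2 > threshold
  pheno <- ifelse(pos1 & pos2, "double_positive",
                  ifelse(pos1, "CD81_only", ifelse(pos2, "CD9_only", "none")))
  out$n_ch1_within <- n1
  out$n_ch2_within <- n2
  out$phenotype <- factor(pheno, levels = phenotype_levels())
  out
}

phenotype_levels <- function() {
  c("CD81_only", "CD9_only", "double_positive", "none")
}

#' Summarize phenotype counts and fractions
#'
#' Totals per phenotype, fractions computed over positive clusters only
#' ("none" clusters excluded, so the three fractions sum to 1), and
#' per-field-of-view mean and SD of the fractions when FOV labels are
#' given.
#'
#' Can also be built directly from count totals via `counts =` when no
#' per-cluster calls are available (e.g. reproducing fractions from
#' published count tables).
#'
#' @param calls data.frame from [call_phenotypes()] (with a `phenotype`
#'   column), or `NULL` when `counts` is given.
#' @param fov optional per-cluster field-of-view labels (the replicate
#'   unit; five FOVs per sample in the reference acquisition design).
#' @param counts optional named numeric vector
#'   `c(CD81_only=, CD9_only=, double_positive=)` of total counts.
#' @return an object of class `"phenotype_summary"`: a list with `counts`
#'   (named, incl. `none`), `fractions` (over positives), `n_positive`,
#'   `n_fov`, `fov_fractions` (FOV x phenotype matrix or `NULL`),
#'   `fov_mean`, `fov_sd`.
#' @export
summarize_phenotypes <- function(calls = NULL, fov = NULL, counts = NULL) {
  pos_levels <- phenotype_levels()[1:3]
  if (is.null(counts)) {
    if (is.null(calls) || nrow(calls) == 0L) stop("need >= 1 phenotype call")
    tab <- table(factor(calls$phenotype, levels = phenotype_levels()))
    counts <- as.numeric(tab)
    names(counts) <- names(tab)
  } else {
    stopifnot(all(pos_levels %in% names(counts)))
    counts <- c(counts[pos_levels], none = unname(
      if ("none" %in% names(counts)) counts[["none"]] else 0))
  }
  n_pos <- sum(counts[pos_levels])
  if (n_pos > 0) {
    fractions <- counts[pos_levels] / n_pos
  } else {
    fractions <- stats::setNames(rep(NA_real_, 3), pos_levels)
    warning("zero positive clusters: fractions undefined")
  }
  fov_fractions <- NULL; fov_mean <- NULL; fov_sd <- NULL; n_fov <- NA_integer_
  if (!is.null(fov) && !is.null(calls)) {
    stopifnot(length(fov) == nrow(calls))
    keep <- calls$phenotype %in% pos_levels
    if (any(keep)) {
      tab <- table(fov[keep], factor(as.character(calls$phenotype[keep]),
                                     levels = pos_levels))
      fov_fractions <- sweep(unclass(tab), 1, rowSums(tab), "/")
      fov_mean <- colMeans(fov_fractions, na.rm = TRUE)
      fov_sd <- apply(fov_fractions, 2, stats::sd, na.rm = TRUE)
      n_fov <- nrow(fov_fractions)
    }
  }
  structure(list(counts = counts, fractions = fractions, n_positive = n_pos,
                 n_fov = n_fov, fov_fractions = fov_fractions,
                 fov_mean = fov_mean, fov_sd = fov_sd),
            class = "phenotype_summary")
}

#' @export
print.phenotype_summary <- function(x, ...) {
  cat("<phenotype_summary>\n")
  cat("  counts:   ", paste(sprintf("%s=%g", names(x$counts), x$counts),
                            collapse = "  "), "\n")
  if (!any(is.na(x$fractions))) {
    cat("  fractions:", paste(sprintf("%s=%.3f", names(x$fractions),
                                      x$fractions), collapse = "  "), "\n")
  }
  if (!is.na(x$n_fov)) cat("  n_fov:    ", x$n_fov, "\n")
  invisible(x)
}

#' Compare phenotype fractions between two groups (two-way ANOVA)
#'
#' A reporting convenience: per-FOV fractions of the two groups (e.g.
#' labelled EV sample vs antibody-only control) are compared with a
#' two-way ANOVA on group and phenotype, including their interaction.  No
#' filtering decision depends on this report.
#'
#' @param sample,control `"phenotype_summary"` objects carrying per-FOV
#'   fractions (build with `fov =` labels).
#' @param alpha significance level for flagging (default 0.05).
#' @return list with the `anova` table, `p_group`, `p_interaction`, and
#'   `significant` (logical, interaction or group p below `alpha`).
#' @export
compare_to_control <- function(sample, control, alpha = 0.05) {
  for (s in list(sample, control)) {
    if (is.null(s$fov_fractions) || nrow(s$fov_fractions) < 2L) {
      stop("need >= 2 fields of view per group for the ANOVA")
    }
  }
  long <- function(s, g) {
    m <- s$fov_fractions
    data.frame(group = g,
               fov = rep(rownames(m), ncol(m)),
               phenotype = rep(colnames(m), each = nrow(m)),
               fraction = as.vector(m))
  }
  df <- rbind(long(sample, "sample"), long(control, "control"))
  df$group <- factor(df$group)
  df$phenotype <- factor(df$phenotype)
  fit <- stats::aov(fraction ~ group * phenotype, data = df)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  p_group <- tab[match("group", rn), "Pr(>F)"]
  p_int <- tab[match("group:phenotype", rn), "Pr(>F)"]
  list(anova = tab, p_group = p_group, p_interaction = p_int,
       significant = isTRUE(min(c(p_group, p_int), na.rm = TRUE) < alpha))
}
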