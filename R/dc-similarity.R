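#' Jaccard similarity of each patient's comorbidity set to each disease
#' cluster
#'
#' `J(patient, DC) = |patient diseases int DC| / |patient diseases un DC|`.
#' By default the patient's disease set is restricted to diseases covered
#' by the cluster partition (the network node set); patients with no
#' qualifying disease get a row of zeros and are flagged.
#'
#' @param dm a [diagnosis_matrix()].
#' @param clusters a `disease_clusters` from [detect_clusters()] (or a
#'   named membership vector).
#' @param restrict_to_clustered restrict patient sets to clustered
#'   diseases (default TRUE).
#' @return patients x clusters numeric matrix in \[0, 1\], with attribute
#'   `empty_patients` naming all-zero rows.
#' @export
patient_dc_jaccard <- function(dm, clusters, restrict_to_clustered = TRUE) {
  stopifnot(inherits(dm, "diagnosis_matrix"))
  memb <- if (inherits(clusters, "disease_clusters"))
    clusters$membership else clusters
  memb <- memb[names(memb) %in% dm$diseases]
  if (!length(memb)) stop("no clustered disease occurs in the matrix")
  occ <- dm$occurrence
  if (restrict_to_clustered)
    occ <- occ[, names(memb), drop = FALSE]
  ids <- sort(unique(memb))
  sizes <- as.numeric(table(factor(memb, levels = ids)))
  # |patient int DC| via sparse product with the cluster indicator
  ind <- Matrix::sparseMatrix(
    i = match(names(memb), colnames(occ)),
    j = match(memb, ids), x = 1,
    dims = c(ncol(occ), length(ids)))
  inter <- as.matrix(occ %*% ind)
  k <- Matrix::rowSums(occ)
  uni <- outer(as.numeric(k), sizes, "+") - inter
  J <- ifelse(uni > 0, inter / uni, 0)
  dimnames(J) <- list(dm$patients, paste0("DC", ids))
  attr(J, "empty_patients") <- dm$patients[k == 0]
  J
}

hl_shift_sign <- function(a, b, max_pairs = 4e6) {
  # sign of the Hodges-Lehmann location shift a - b; for very large
  # cohorts the sign of the Mann-Whitney U displacement is used, which
  # agrees with the HL sign direction
  if (length(a) * length(b) <= max_pairs) {
    sign(stats::median(rep(a, times = length(b)) -
                         rep(b, each = length(a))))
  } else {
    r <- rank(c(a, b))
    u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
    sign(u - length(a) * length(b) / 2)
  }
}

#' Contrast patient cohorts on disease-cluster similarity
#'
#' Per disease cluster, applies an unpaired two-sided Wilcoxon rank-sum
#' test to the patient-cluster Jaccard values between two cohort levels
#' of a covariate. `signed_logp = -log10(p) * sign(shift)` where the
#' shift is the Hodges-Lehmann location estimate of cohort_a minus
#' cohort_b, so positive values indicate higher cluster similarity in the
#' first cohort. BH-adjusted p-values across clusters are reported
#' alongside the raw ones.
#'
#' @param jmat matrix from [patient_dc_jaccard()].
#' @param dm the matching [diagnosis_matrix()].
#' @param covariate covariate column name.
#' @param level_a,level_b the two cohort levels to contrast.
#' @return data.frame per cluster: `cluster`, `cohort_a`, `cohort_b`,
#'   `statistic` (Wilcoxon W), `p_value`, `q_bh`, `signed_logp`.
#' @export
contrast_cohorts <- function(jmat, dm, covariate, level_a, level_b) {
  stopifnot(inherits(dm, "diagnosis_matrix"),
            covariate %in% names(dm$covariates))
  v <- as.character(dm$covariates[rownames(jmat), covariate])
  ia <- which(!is.na(v) & v == level_a)
  ib <- which(!is.na(v) & v == level_b)
  if (!length(ia) || !length(ib)) stop("a contrast level is empty")
  res <- lapply(colnames(jmat), function(cl) {
    a <- jmat[ia, cl]; b <- jmat[ib, cl]
    if (all(c(a, b) == c(a, b)[1])) {
      return(data.frame(cluster = cl, cohort_a = level_a,
                        cohort_b = level_b, statistic = NA_real_,
                        p_value = 1, signed_logp = 0))
    }
    # exact enumeration for small tie-free samples, normal approximation
    # otherwise (wilcox.test's own switch)
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    s <- hl_shift_sign(a, b)
    data.frame(cluster = cl, cohort_a = level_a, cohort_b = level_b,
               statistic = unname(wt$statistic), p_value = wt$p.value,
               signed_logp = -log10(pmax(wt$p.value, 1e-300)) * s)
  })
  out <- do.call(rbind, res)
  out$q_bh <- bh_adjust(out$p_value)
  out <- out[, c("cluster", "cohort_a", "cohort_b", "statistic",
                 "p_value", "q_bh", "signed_logp")]
  rownames(out) <- NULL
  out
}
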