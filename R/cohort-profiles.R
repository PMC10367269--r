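#' Multiple correspondence analysis of comorbidity profiles
#'
#' Correspondence analysis of the complete disjunctive indicator matrix
#' (each disease coded by two categories, presence and absence), via the
#' SVD of the standardized residual matrix
#' `D_r^{-1/2} (P - r c^T) D_c^{-1/2}`. Constant disease columns carry no
#' inertia and are dropped with a warning. Patient principal coordinates
#' and per-dimension inertia percentages (on the indicator-matrix total
#' inertia) are returned; the decomposition is computed from the
#' cross-product of the residual matrix, so cost scales with the number
#' of disease categories, not patients.
#'
#' @param dm a [diagnosis_matrix()].
#' @param n_dims number of dimensions to keep (default `min(50, rank)`).
#' @return an object of class `mca_result`: list with `coordinates`
#'   (patients x dims), `dim_inertia` (percent per dimension, decreasing),
#'   `total_inertia`, `singular_values`.
#' @export
run_mca <- function(dm, n_dims = 50) {
  stopifnot(inherits(dm, "diagnosis_matrix"))
  X <- as.matrix(dm$occurrence)
  if (ncol(X) < 2) stop("need at least 2 diseases")
  const <- apply(X, 2, function(v) all(v == v[1]))
  if (any(const)) {
    warning("dropping constant disease columns: ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  n <- nrow(X); J <- ncol(X)
  Z <- cbind(X, 1 - X)                       # complete disjunctive coding
  colnames(Z) <- c(paste0(colnames(X), ":1"), paste0(colnames(X), ":0"))
  gt <- sum(Z)
  P <- Z / gt
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - tcrossprod(r, cc)) / sqrt(r)     # D_r^{-1/2} (P - r c')
  S <- sweep(S, 2, sqrt(cc), "/")            # ... D_c^{-1/2}
  ee <- eigen(crossprod(S), symmetric = TRUE)
  pos <- ee$values > max(ee$values, 0) * 1e-12
  sv <- sqrt(pmax(ee$values[pos], 0))
  V <- ee$vectors[, pos, drop = FALSE]
  k <- min(n_dims, length(sv))
  # principal row coordinates F = D_r^{-1/2} U Sigma = D_r^{-1/2} S V
  Fc <- (S %*% V[, seq_len(k), drop = FALSE]) / sqrt(r)
  rownames(Fc) <- rownames(X)
  colnames(Fc) <- paste0("dim", seq_len(k))
  total <- sum(S^2)
  structure(list(coordinates = Fc,
                 dim_inertia = 100 * sv[seq_len(k)]^2 / total,
                 total_inertia = total,
                 singular_values = sv),
            class = "mca_result")
}

#' @export
print.mca_result <- function(x, ...) {
  cat("mca_result:", nrow(x$coordinates), "patients,",
      ncol(x$coordinates), "dimensions kept\n")
  cat("  leading inertia %:",
      paste(round(utils::head(x$dim_inertia, 5), 2), collapse = ", "), "\n")
  invisible(x)
}

#' Covariate-associated variance in comorbidity profiles
#'
#' Regresses each MCA dimension's patient coordinates on a covariate
#' (ordinary least squares; factors enter as factors and significance is
#' the overall F-test p). The covariate's explained variance is the sum
#' of inertia percentages over dimensions with p below `p_cut`.
#'
#' @param mca an [run_mca()] result.
#' @param dm the matching [diagnosis_matrix()].
#' @param covariate covariate column name.
#' @param p_cut per-dimension significance cutoff (default 0.05).
#' @return list with `covariate`, `explained_pct`, `significant_dims`,
#'   `p_values`.
#' @export
variance_attribution <- function(mca, dm, covariate, p_cut = 0.05) {
  stopifnot(inherits(mca, "mca_result"), inherits(dm, "diagnosis_matrix"),
            covariate %in% names(dm$covariates))
  v <- dm$covariates[rownames(mca$coordinates), covariate]
  if (any(is.na(v))) stop("covariate has missing values")
  if (length(unique(v)) < 2)
    return(list(covariate = covariate, explained_pct = 0,
                significant_dims = integer(0), p_values = numeric(0)))
  pv <- vapply(seq_len(ncol(mca$coordinates)), function(j) {
    fit <- stats::lm(mca$coordinates[, j] ~ v)
    f <- summary(fit)$fstatistic
    stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  }, numeric(1))
  sig <- which(pv < p_cut)
  list(covariate = covariate,
       explained_pct = sum(mca$dim_inertia[sig]),
       significant_dims = sig, p_values = pv)
}

stratified_foldid <- function(y, folds, seed) {
  set.seed(seed)
  id <- integer(length(y))
  for (l in unique(y)) {
    ii <- which(y == l)
    if (length(ii) < folds)
      stop("class '", l, "' has fewer members than folds")
    id[ii] <- sample(rep(seq_len(folds), length.out = length(ii)))
  }
  id
}

#' Elastic-net comorbidity classifier of a two-class label
#'
#' Fits a regularized logistic regression of the subtype label on the
#' binary disease matrix, tuning the penalty strength over a log-scale
#' grid by stratified cross-validated AUROC. Positive coefficients pull
#' towards the second factor level of `labels`.
#'
#' @param dm a [diagnosis_matrix()].
#' @param labels two-level factor/character, one per patient (name of a
#'   covariate column also accepted).
#' @param l1_ratio elastic-net mixing (glmnet alpha; 1 = lasso).
#' @param folds number of CV folds (stratified).
#' @param seed integer seed.
#' @param nlambda penalty grid size (default 20).
#' @return list with `coefficients` (named, intercept excluded),
#'   `nonzero` (names of nonzero-coefficient diseases ordered by
#'   decreasing |coefficient|), `cv_auroc`, `lambda`, `levels`.
#' @export
fit_profile_classifier <- function(dm, labels, l1_ratio = 0.5, folds = 5,
                                   seed = 1L, nlambda = 20) {
  stopifnot(inherits(dm, "diagnosis_matrix"))
  if (length(labels) == 1 && labels %in% names(dm$covariates))
    labels <- dm$covariates[[labels]]
  y <- factor(labels)
  keep <- !is.na(y)
  y <- droplevels(y[keep])
  if (nlevels(y) != 2) stop("labels must have exactly two levels")
  x <- dm$occurrence[keep, , drop = FALSE]
  foldid <- stratified_foldid(y, folds, seed)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = l1_ratio,
                          type.measure = "auc", foldid = foldid,
                          nlambda = nlambda, standardize = FALSE)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
  co <- co[setdiff(names(co), "(Intercept)")]
  nz <- co[co != 0]
  list(coefficients = co,
       nonzero = names(nz)[order(-abs(nz))],
       cv_auroc = max(cv$cvm),
       lambda = cv$lambda.min,
       levels = levels(y))
}

#' Forward selection of a subtype-discriminative comorbidity profile
#'
#' Grows the feature set along `ranked_features` (diseases ordered by
#' decreasing absolute elastic-net coefficient) in increments of `step`,
#' refitting an L1-regularized logistic model at each size and recording
#' its cross-validated AUROC. The selected profile is the smallest size
#' whose AUROC is within `tolerance` of the maximum over all sizes;
#' diseases are assigned to one cohort or the other by the sign of their
#' coefficient in the selected model.
#'
#' @param dm a [diagnosis_matrix()].
#' @param labels two-level labels as in [fit_profile_classifier()].
#' @param ranked_features ordered disease codes to grow along.
#' @param step increment size (default 5).
#' @param folds CV folds.
#' @param seed integer seed.
#' @param tolerance AUROC plateau tolerance (default 0.002).
#' @return an object of class `comorbidity_profile`: list with
#'   `assignments` (data.frame `disease`, `cohort`, `coefficient`),
#'   `model_size`, `cv_auroc`, `path` (data.frame `size`, `cv_auroc`),
#'   `levels`.
#' @export
forward_select <- function(dm, labels, ranked_features, step = 5,
                           folds = 5, seed = 1L, tolerance = 0.002) {
  stopifnot(inherits(dm, "diagnosis_matrix"))
  if (!length(ranked_features)) stop("ranked_features is empty")
  stopifnot(all(ranked_features %in% dm$diseases))
  if (length(labels) == 1 && labels %in% names(dm$covariates))
    labels <- dm$covariates[[labels]]
  y <- factor(labels)
  keep <- !is.na(y)
  y <- droplevels(y[keep])
  if (nlevels(y) != 2) stop("labels must have exactly two levels")
  x_all <- dm$occurrence[keep, , drop = FALSE]
  foldid <- stratified_foldid(y, folds, seed)
  sizes <- unique(c(seq(min(step, length(ranked_features)),
                        length(ranked_features), by = step),
                    length(ranked_features)))
  fit_at <- function(size) {
    feats <- ranked_features[seq_len(size)]
    x <- x_all[, feats, drop = FALSE]
    if (size == 1) x <- cbind(x, intercept_dummy = 0)  # glmnet needs >=2 cols
    glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                      type.measure = "auc", foldid = foldid,
                      standardize = FALSE)
  }
  aucs <- vapply(sizes, function(s) max(fit_at(s)$cvm), numeric(1))
  best <- sizes[min(which(aucs >= max(aucs) - tolerance))]
  cv <- fit_at(best)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
  co <- co[intersect(names(co), ranked_features)]
  co <- co[co != 0]
  lv <- levels(y)
  assignments <- data.frame(
    disease = names(co),
    cohort = ifelse(co > 0, lv[2], lv[1]),
    coefficient = unname(co))
  assignments <- assignments[order(-abs(assignments$coefficient)), ]
  rownames(assignments) <- NULL
  structure(list(assignments = assignments,
                 model_size = nrow(assignments),
                 cv_auroc = max(cv$cvm),
                 path = data.frame(size = sizes, cv_auroc = aucs),
                 levels = lv),
            class = "comorbidity_profile")
}

#' @export
print.comorbidity_profile <- function(x, ...) {
  cat("comorbidity_profile:", x$model_size, "diseases, CV AUROC",
      round(x$cv_auroc, 3), "\n")
  tab <- table(x$assignments$cohort)
  cat("  assignment:", paste(names(tab), tab, sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

#' Diseases of a profile assigned to one cohort
#' @param profile a `comorbidity_profile`.
#' @param cohort cohort label (one of `profile$levels`).
#' @return character vector of disease codes.
#' @export
profile_diseases <- function(profile, cohort) {
  stopifnot(inherits(profile, "comorbidity_profile"))
  profile$assignments$disease[profile$assignments$cohort == cohort]
}
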