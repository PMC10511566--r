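# Design matrices for the normative models.
#
# LMR: intercept + linear age + linear education + gender + language
# dummies (English reference). GAM: the age and education columns are
# replaced by penalized cubic B-spline smooths (basis size 8, equally
# spaced knots over the training range, second-order difference
# penalty), each centered via a sum-to-zero-over-training-rows
# constraint so the smooths are identifiable next to the intercept. The
# linear trend lives in the penalty null space and so carries a flat
# prior, matching the flat priors on the parametric coefficients.

#' Specify a normative model
#'
#' @param test_id Battery test id.
#' @param form \code{"LMR"} (linear) or \code{"GAM"} (penalized
#'   additive smooths of age and education).
#' @param predictors Subset of \code{c("age", "education", "gender",
#'   "language")}.
#' @param k Spline basis size per smooth (GAM only).
#' @return A list of class \code{"model_spec"}.
#' @export
model_spec <- function(test_id,
                       form = c("GAM", "LMR"),
                       predictors = c("age", "education", "gender",
                                      "language"),
                       k = 8) {
  form <- match.arg(form)
  predictors <- match.arg(predictors,
                          c("age", "education", "gender", "language"),
                          several.ok = TRUE)
  if (form == "GAM" && !any(c("age", "education") %in% predictors))
    stop("a GAM needs at least one of age/education as predictor")
  stopifnot(k >= 5)
  structure(list(test_id = toupper(test_id), form = form,
                 predictors = predictors, k = k),
            class = "model_spec")
}

# Cubic B-spline basis with k functions on [lo, hi]: boundary knots
# repeated 4x, k - 4 equally spaced interior knots. Rows sum to 1
# (partition of unity) everywhere inside [lo, hi].
bspline_knots <- function(lo, hi, k) {
  interior <- if (k > 4) seq(lo, hi, length.out = k - 2)[-c(1, k - 2)]
              else numeric(0)
  c(rep(lo, 4), interior, rep(hi, 4))
}

bspline_basis <- function(x, knots) {
  lo <- knots[4]; hi <- knots[length(knots) - 3]
  splines::splineDesign(knots, pmin(pmax(x, lo), hi), ord = 4)
}

# one smooth term: constrained basis Z = B Q, penalty Q' D'D Q
.make_smooth <- function(x, k, label) {
  lo <- min(x); hi <- max(x)
  knots <- bspline_knots(lo, hi, k)
  B <- bspline_basis(x, knots)
  C <- colMeans(B)
  Q <- qr.Q(qr(matrix(C, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
  D <- diff(diag(k), differences = 2)
  S <- crossprod(D %*% Q)
  list(label = label, knots = knots, Q = Q, S = S,
       rank = k - 2, range = c(lo, hi))
}

.smooth_cols <- function(sm, x) bspline_basis(x, sm$knots) %*% sm$Q

#' Build the design for a normative model from training data
#'
#' Constructs the training design matrix and freezes everything needed
#' to reproduce it at prediction time: spline knots and constraint for
#' each smooth, the observed language levels (English reference) and
#' training ranges.
#'
#' @param spec A \code{\link{model_spec}}.
#' @param data Data.frame with \code{age}, \code{edu_years}, \code{sex},
#'   \code{lang} as required by the predictors.
#' @return A list of class \code{"norm_design"} with the training matrix
#'   in \code{$X}, penalty descriptors in \code{$penalties} (column
#'   indices, penalty matrix, rank) and the frozen builder state.
#' @export
build_design <- function(spec, data) {
  d <- list(spec = spec, smooths = list(), lang_levels = NULL,
            train_range = list())
  cols <- list(`(Intercept)` = rep(1, nrow(data)))
  penalties <- list()
  if ("age" %in% spec$predictors) {
    d$train_range$age <- range(data$age)
    if (spec$form == "GAM") {
      sm <- .make_smooth(data$age, spec$k, "s(age)")
      d$smooths$age <- sm
      Z <- .smooth_cols(sm, data$age)
      colnames(Z) <- paste0("s(age).", seq_len(ncol(Z)))
      cols$age_smooth <- Z
      penalties$age <- list(prefix = "s(age).", S = sm$S,
                            rank = sm$rank)
    } else {
      cols$age <- data$age
    }
  }
  if ("education" %in% spec$predictors) {
    d$train_range$edu <- range(data$edu_years)
    if (spec$form == "GAM") {
      sm <- .make_smooth(data$edu_years, spec$k, "s(edu)")
      d$smooths$edu <- sm
      Z <- .smooth_cols(sm, data$edu_years)
      colnames(Z) <- paste0("s(edu).", seq_len(ncol(Z)))
      cols$edu_smooth <- Z
      penalties$edu <- list(prefix = "s(edu).", S = sm$S,
                            rank = sm$rank)
    } else {
      cols$edu_years <- data$edu_years
    }
  }
  if ("gender" %in% spec$predictors)
    cols$genderf <- as.numeric(data$sex == "f")
  if ("language" %in% spec$predictors) {
    seen <- unique(as.character(data$lang))
    ref <- if ("EN" %in% seen) "EN" else seen[1]
    levels <- c(ref, sort(setdiff(seen, ref)))
    d$lang_levels <- levels
    f <- factor(data$lang, levels = levels)
    L <- stats::model.matrix(~ f)[, -1, drop = FALSE]
    colnames(L) <- paste0("lang", levels[-1])
    cols$language <- L
  }
  X <- do.call(cbind, lapply(cols, as.matrix))
  nm <- unlist(lapply(names(cols), function(g) {
    v <- cols[[g]]
    if (is.matrix(v)) colnames(v) else g
  }))
  nm[1] <- "(Intercept)"
  colnames(X) <- nm
  d$X <- X
  for (j in names(penalties))
    penalties[[j]]$cols <- which(startsWith(nm, penalties[[j]]$prefix))
  d$penalties <- penalties
  structure(d, class = "norm_design")
}

#' Evaluate a frozen design at new data
#'
#' @param design A \code{\link{build_design}} result.
#' @param newdata Data.frame with the predictor columns.
#' @return Numeric matrix with the same columns as the training design.
#'   Unseen language levels are an error; age/education outside the
#'   training range are clamped for the spline evaluation (the
#'   prediction functions flag them as extrapolation).
#' @export
design_matrix <- function(design, newdata) {
  spec <- design$spec
  n <- nrow(newdata)
  cols <- list(matrix(1, n, 1))
  if ("age" %in% spec$predictors) {
    cols <- c(cols, list(
      if (spec$form == "GAM")
        .smooth_cols(design$smooths$age, newdata$age)
      else matrix(newdata$age, ncol = 1)))
  }
  if ("education" %in% spec$predictors) {
    cols <- c(cols, list(
      if (spec$form == "GAM")
        .smooth_cols(design$smooths$edu, newdata$edu_years)
      else matrix(newdata$edu_years, ncol = 1)))
  }
  if ("gender" %in% spec$predictors)
    cols <- c(cols, list(matrix(as.numeric(newdata$sex == "f"),
                                ncol = 1)))
  if ("language" %in% spec$predictors) {
    unseen <- setdiff(unique(as.character(newdata$lang)),
                      design$lang_levels)
    if (length(unseen))
      stop("language level(s) not seen in training: ",
           paste(unseen, collapse = ", "))
    f <- factor(newdata$lang, levels = design$lang_levels)
    cols <- c(cols, list(stats::model.matrix(~ f)[, -1, drop = FALSE]))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- colnames(design$X)
  X
}

#' Flag rows outside the fitted age/education range
#' @keywords internal
is_extrapolation <- function(design, newdata) {
  out <- rep(FALSE, nrow(newdata))
  tr <- design$train_range
  if (!is.null(tr$age))
    out <- out | newdata$age < tr$age[1] | newdata$age > tr$age[2]
  if (!is.null(tr$edu))
    out <- out | newdata$edu_years < tr$edu[1] |
      newdata$edu_years > tr$edu[2]
  out
}
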