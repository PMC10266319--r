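#' Specify a regression model for an inflated count outcome
#'
#' The four supported families, in increasing order of structural
#' complexity:
#' \describe{
#'   \item{`linear`}{Gaussian regression of the mean; no bounds, so
#'     predictions outside the valid value space can occur.}
#'   \item{`hurdle_nb`}{Two-part hurdle: a logistic sub-model for
#'     `P(Y = 0)` and a zero-truncated negative-binomial sub-model for the
#'     positive counts.  Requires the days scale with deaths coded 0 (or
#'     actual values).}
#'   \item{`zoib`}{Three-part zero-one-inflated beta for the outcome as a
#'     proportion of `max_days`: logistic sub-models for
#'     `P(Y in {0, 1})` and `P(Y = 1 | boundary)`, and a beta sub-model
#'     (mean-precision parameterisation, logit link) for the interior.}
#'   \item{`cumlogit`}{Cumulative (proportional-odds) logistic regression
#'     over the distinct observed values as ordered categories, with the -1
#'     death category supported.}
#' }
#'
#' @param family Model family (see above).
#' @param terms Character vector of predictor column names; the treatment
#'   `arm` is normally included.  `NULL` or `character(0)` gives an
#'   intercept-only model.  Covariates enter every sub-model by default.
#' @param sub_terms Optional named list overriding `terms` per sub-model;
#'   valid names are `mean` (linear), `zero`/`count` (hurdle),
#'   `boundary`/`one`/`mu` (zoib), `location` (cumlogit).
#' @return An object of class `dawols_model_spec`.
#' @examples
#' model_spec("hurdle_nb")
#' model_spec("hurdle_nb", sub_terms = list(zero = NULL)) # intercept-only hurdle part
#' @export
model_spec <- function(family = c("linear", "hurdle_nb", "zoib", "cumlogit"),
                       terms = "arm", sub_terms = NULL) {
  family <- match.arg(family)
  if (length(terms) == 0) terms <- NULL
  parts <- .parts_of(family)
  if (!is.null(sub_terms))
    .assert(all(names(sub_terms) %in% parts),
            "sub_terms names must be among: %s", paste(parts, collapse = ", "))
  structure(list(family = family, terms = terms, sub_terms = sub_terms),
            class = "dawols_model_spec")
}

.parts_of <- function(family) switch(
  family,
  linear = "mean",
  hurdle_nb = c("zero", "count"),
  zoib = c("boundary", "one", "mu"),
  cumlogit = "location"
)

## family / outcome-spec compatibility (ModelSpec invariants)
.check_family_scale <- function(family, spec) {
  ok <- switch(family,
    linear = TRUE,
    hurdle_nb = spec$scale == "days" &&
      spec$death_handling %in% c("penalize_zero", "actual"),
    zoib = spec$scale == "proportion",
    cumlogit = spec$scale == "ordinal")
  if (!ok)
    stop("family \"", family, "\" is incompatible with scale \"", spec$scale,
         "\" / death_handling \"", spec$death_handling, "\": hurdle_nb needs ",
         "the days scale with deaths coded 0 or actual values; zoib needs ",
         "the proportion scale; cumlogit needs the ordinal scale",
         call. = FALSE)
  invisible(TRUE)
}

## one design matrix per sub-model; cumlogit has no intercept (absorbed by
## the cutpoints)
.build_design <- function(mspec, data) {
  out <- list()
  for (p in .parts_of(mspec$family)) {
    trm <- if (!is.null(mspec$sub_terms) && p %in% names(mspec$sub_terms))
      mspec$sub_terms[[p]] else mspec$terms
    f <- if (length(trm)) stats::reformulate(trm) else ~1
    X <- stats::model.matrix(f, data = data)
    if (mspec$family == "cumlogit")
      X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
    out[[p]] <- X
  }
  out
}

#' @export
print.dawols_model_spec <- function(x, ...) {
  cat("<model spec> family:", x$family, " terms:",
      if (is.null(x$terms)) "(intercept only)"
      else paste(x$terms, collapse = " + "), "\n")
  invisible(x)
}
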