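#' Modality specification
#'
#' Describes a molecular modality and the scale transform applied to it before
#' factorization and network training. Count-like modalities (RNA, ATAC,
#' proteomics) are transformed with `log1p` so zero counts stay representable;
#' DNA-methylation beta values in \[0, 1\] are transformed with a negative
#' logarithm after clipping away exact zeros.
#'
#' @param name One of `"rna"`, `"atac"`, `"proteomics"`, `"dnam"`.
#' @param beta_eps Lower clip applied to DNAm beta values before `-log()`;
#'   ignored for other modalities.
#' @return An object of class `modality_spec` with fields `name`, `transform`
#'   (`"log1p"` or `"neglog"`) and `beta_eps`.
#' @examples
#' modality_spec("atac")
#' modality_spec("dnam")
#' @export
modality_spec <- function(name = c("rna", "atac", "proteomics", "dnam"),
                          beta_eps = 1e-6) {
  name <- match.arg(name)
  stopifnot(is.numeric(beta_eps), length(beta_eps) == 1L, beta_eps > 0, beta_eps < 1)
  structure(
    list(
      name = name,
      transform = if (name == "dnam") "neglog" else "log1p",
      beta_eps = beta_eps
    ),
    class = "modality_spec"
  )
}

#' @export
print.modality_spec <- function(x, ...) {
  cat(sprintf("<modality_spec> %s (transform: %s)\n", x$name, x$transform))
  invisible(x)
}

as_modality_spec <- function(spec) {
  if (inherits(spec, "modality_spec")) return(spec)
  if (is.character(spec) && length(spec) == 1L) return(modality_spec(spec))
  stop("`spec` must be a modality_spec or a modality name", call. = FALSE)
}

#' Forward scale transform for a modality
#'
#' Applies `log1p` elementwise for count-like modalities and `-log(beta)` for
#' DNAm, after clipping betas to `[beta_eps, 1]`. Output is finite and
#' nonnegative.
#'
#' @param values Numeric vector or matrix of raw-scale values.
#' @param spec A [modality_spec()] (or a modality name).
#' @return Transformed values with the same shape.
#' @examples
#' transform_forward(c(0, 1, 10), modality_spec("rna"))
#' transform_forward(0.5, modality_spec("dnam")) # -log(0.5)
#' @export
transform_forward <- function(values, spec) {
  spec <- as_modality_spec(spec)
  if (any(!is.finite(values))) stop("non-finite values in input", call. = FALSE)
  if (spec$transform == "neglog") {
    if (any(values < 0) || any(values > 1)) {
      stop("dnam beta values must lie in [0, 1]", call. = FALSE)
    }
    -log(pmax(values, spec$beta_eps))
  } else {
    if (any(values < 0)) {
      stop(sprintf("negative entries are invalid for modality '%s'", spec$name),
           call. = FALSE)
    }
    log1p(values)
  }
}

#' Inverse scale transform for a modality
#'
#' Exact inverse of [transform_forward()] away from the beta clipping region;
#' DNAm output is re-clipped to \[0, 1\].
#'
#' @inheritParams transform_forward
#' @param values Numeric vector or matrix on the transformed scale.
#' @return Raw-scale values with the same shape.
#' @examples
#' transform_inverse(transform_forward(c(0, 3, 7), "atac"), "atac")
#' @export
transform_inverse <- function(values, spec) {
  spec <- as_modality_spec(spec)
  if (any(!is.finite(values))) stop("non-finite values in input", call. = FALSE)
  if (spec$transform == "neglog") {
    pmin(pmax(exp(-values), 0), 1)
  } else {
    expm1(values)
  }
}
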