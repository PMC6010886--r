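#' Specify a multi-tree rate model
#'
#' Defines which speciation and extinction rates are shared or free across
#' the `m` trees of a dataset. The available models form a nested family:
#'
#' * `"equal"` — one shared speciation rate and one shared extinction rate
#'   across all trees (2 parameters); the usual null model.
#' * `"free"` — each tree has its own speciation and extinction rate
#'   (`2m` parameters).
#' * `"free-speciation"` — per-tree speciation rates, one shared extinction
#'   rate (`m + 1` parameters).
#' * `"free-extinction"` — one shared speciation rate, per-tree extinction
#'   rates (`m + 1` parameters).
#' * `"yule-equal"` — pure-birth (`mu = 0`) with one shared speciation rate
#'   (1 parameter).
#' * `"yule-free"` — pure-birth with per-tree speciation rates (`m`
#'   parameters).
#' * `"grouped"` — trees are assigned a priori to `g` rate classes; each
#'   class has its own speciation and extinction rate (`2g` parameters).
#'   Requires `groups`.
#'
#' @param name Model name, one of the strings above.
#' @param m Number of trees the model applies to.
#' @param groups For `"grouped"`: a vector of length `m` assigning each tree
#'   to a rate class (any atomic labels; coerced to consecutive integers).
#' @return An object of class `model_spec` with fields `name`, `m`, `groups`,
#'   `k` (free-parameter count), and the internal constraint maps
#'   `lambda_class` / `mu_class` (integer class of each tree's rate;
#'   `mu_class = 0L` means extinction fixed at zero).
#' @export
model_spec <- function(name = c("equal", "free", "free-speciation",
                                "free-extinction", "yule-equal", "yule-free",
                                "grouped"),
                       m, groups = NULL) {
  name <- match.arg(name)
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (name == "grouped") {
    if (is.null(groups)) stop("model 'grouped' requires groups", call. = FALSE)
    if (length(groups) != m) {
      stop("groups must have length m = ", m, call. = FALSE)
    }
    groups <- as.integer(factor(groups))
    g <- max(groups)
  } else {
    if (!is.null(groups)) {
      stop("groups are only meaningful for the 'grouped' model", call. = FALSE)
    }
    g <- NA_integer_
  }
  maps <- switch(name,
    "equal"           = list(lam = rep(1L, m), mu = rep(1L, m)),
    "free"            = list(lam = seq_len(m), mu = seq_len(m)),
    "free-speciation" = list(lam = seq_len(m), mu = rep(1L, m)),
    "free-extinction" = list(lam = rep(1L, m), mu = seq_len(m)),
    "yule-equal"      = list(lam = rep(1L, m), mu = rep(0L, m)),
    "yule-free"       = list(lam = seq_len(m), mu = rep(0L, m)),
    "grouped"         = list(lam = groups,     mu = groups)
  )
  k <- switch(name,
    "equal"           = 2L,
    "free"            = 2L * m,
    "free-speciation" = m + 1L,
    "free-extinction" = m + 1L,
    "yule-equal"      = 1L,
    "yule-free"       = m,
    "grouped"         = 2L * g
  )
  structure(
    list(name = name, m = m, groups = groups, k = k,
         lambda_class = maps$lam, mu_class = maps$mu),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec '%s': m = %d trees, k = %d free parameter(s)\n",
              x$name, x$m, x$k))
  if (!is.null(x$groups)) {
    cat("  groups:", paste(x$groups, collapse = ", "), "\n")
  }
  invisible(x)
}

# Structural nesting of the model family: for each alternative, the models
# that are special cases of it. Grouped models additionally require that the
# null is 'equal' (or Yule-equal) — finer/other groupings are not checked.
.nested_nulls <- list(
  "free"            = c("equal", "free-speciation", "free-extinction",
                        "grouped", "yule-free", "yule-equal"),
  "free-speciation" = c("equal", "yule-free", "yule-equal"),
  "free-extinction" = c("equal", "yule-equal"),
  "grouped"         = c("equal", "yule-equal"),
  "yule-free"       = c("yule-equal"),
  "equal"           = c("yule-equal")
)

is_nested <- function(null_model, alt_model) {
  stopifnot(inherits(null_model, "model_spec"), inherits(alt_model, "model_spec"))
  if (null_model$m != alt_model$m) return(FALSE)
  nulls <- .nested_nulls[[alt_model$name]]
  (!is.null(nulls)) && null_model$name %in% nulls &&
    alt_model$k > null_model$k
}
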