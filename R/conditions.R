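## Parameter sets (log-scale storage) and condition maps: shared vs
## condition-specific resolution of parameters across SD / WD / patients.

#' Create a log-scale parameter set
#'
#' Parameters are stored on the natural-log scale to guarantee positivity of
#' native values; `parameter_values()` returns the native scale.
#'
#' @param values Named numeric vector of native-scale (strictly positive)
#'   parameter values.
#' @return Object of class `parameter_set`.
#' @export
parameter_set <- function(values) {
  if (any(values <= 0)) stop("native-scale parameter values must be positive")
  structure(list(log_values = log(values)), class = "parameter_set")
}

#' Native-scale values of a parameter set
#' @param ps A `parameter_set`.
#' @return Named numeric vector.
#' @export
parameter_values <- function(ps) exp(ps$log_values)

#' Create a condition map
#'
#' Declares which parameters are condition-specific and stores per-condition
#' overrides and experimental inputs.
#'
#' @param conditions Character vector of condition labels (e.g. `c("SD","WD")`).
#' @param specific Character vector of condition-specific parameter names; all
#'   others are shared.
#' @param overrides Named list: for each condition, a named numeric vector of
#'   native-scale values for (a subset of) the specific parameters.
#' @param inputs Named list: for each condition, a list with `dose` (ng/ml) and
#'   optionally `t_start`.
#' @return Object of class `condition_map`.
#' @export
condition_map <- function(conditions, specific = character(),
                          overrides = list(), inputs = list()) {
  bad <- setdiff(names(overrides), conditions)
  if (length(bad)) stop("overrides for unknown conditions: ",
                        paste(bad, collapse = ", "))
  for (cn in names(overrides)) {
    extra <- setdiff(names(overrides[[cn]]), specific)
    if (length(extra))
      stop("override of shared parameter(s) ", paste(extra, collapse = ", "),
           " in condition ", cn)
  }
  structure(list(conditions = conditions, specific = specific,
                 overrides = overrides, inputs = inputs),
            class = "condition_map")
}

#' Resolve parameters for one condition
#'
#' Shared parameters take the base value for every condition;
#' condition-specific parameters take the override registered for the
#' requested condition (falling back to the base value if no override is
#' registered).
#'
#' @param params A `parameter_set` (base values).
#' @param cmap A `condition_map`.
#' @param condition Condition label.
#' @return Named native-scale numeric vector with one value per parameter.
#' @export
resolve_parameters <- function(params, cmap, condition) {
  if (!condition %in% cmap$conditions)
    stop("unknown condition: ", condition)
  v <- parameter_values(params)
  ov <- cmap$overrides[[condition]]
  if (!is.null(ov)) {
    unknown <- setdiff(names(ov), names(v))
    if (length(unknown))
      stop("unresolved parameter(s): ", paste(unknown, collapse = ", "))
    v[names(ov)] <- ov
  }
  v
}

#' The reference diet hypothesis: 12 dysregulated parameters
#'
#' The basal MET phosphorylation rate plus the abundances of the eleven
#' modeled proteins are diet-specific; everything else is shared between
#' standard-diet and Western-diet hepatocytes.
#'
#' @return Character vector of the 12 parameter names.
#' @export
dysregulated_parameters <- function() c("k_basal_MET", abundance_parameters())
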