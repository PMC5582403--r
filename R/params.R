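#' Pre/post-stimulus parameter set
#'
#' A parameter-stimulus hypothesis pairs an unstimulated parameter vector
#' `theta_U` (rates before induction, per minute) with a stimulated vector
#' `theta_S` that differs from it only on the parameters named in
#' `stimulus`. Parameters listed in `fixed` (typically the mRNA degradation
#' rate `delta`, measured independently) are held constant during inference.
#' Each free non-stimulus parameter contributes one free value and each free
#' stimulus parameter contributes two (pre and post), so the free-parameter
#' count is `|parameters \ fixed| + |stimulus \ fixed|`.
#'
#' The free-parameter vector ordering is fixed and documented: parameters in
#' `model$parameter_names` order, skipping fixed ones; a stimulus parameter
#' `x` expands in place to `x_U` then `x_S`.
#'
#' @param unstimulated Named numeric vector of pre-stimulus values covering
#'   every model parameter.
#' @param stimulated Named numeric vector giving post-stimulus values for the
#'   stimulus-affected parameters only (its names define `stimulus`).
#' @param fixed Character vector of parameter names held fixed (not sampled).
#' @param model A `gene_model`; defaults to the diploid two-state model.
#' @return A `param_set` object.
#' @examples
#' ps <- parameter_set(
#'   unstimulated = c(k1 = 0.01, k0 = 0.1, mu0 = 0.01, mu1 = 2, delta = 0.05),
#'   stimulated = c(k1 = 1), fixed = "delta"
#' )
#' free_names(ps)
#' @export
parameter_set <- function(unstimulated, stimulated = numeric(0),
                          fixed = "delta", model = two_state_model(2)) {
  pn <- model$parameter_names
  miss <- setdiff(pn, names(unstimulated))
  if (length(miss)) {
    stop("`unstimulated` is missing parameter(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  stimulus <- names(stimulated)
  if (!all(stimulus %in% pn)) {
    stop("unknown stimulus parameter(s): ",
         paste(setdiff(stimulus, pn), collapse = ", "), call. = FALSE)
  }
  if (!all(fixed %in% pn)) {
    stop("unknown fixed parameter(s): ",
         paste(setdiff(fixed, pn), collapse = ", "), call. = FALSE)
  }
  if (length(intersect(stimulus, fixed))) {
    stop("a parameter cannot be both fixed and stimulus-affected.",
         call. = FALSE)
  }
  values_U <- unstimulated[pn]
  values_S <- values_U
  values_S[stimulus] <- stimulated
  if (any(c(values_U, values_S) < 0)) {
    stop("all parameter values must be nonnegative.", call. = FALSE)
  }
  structure(
    list(values_U = values_U, values_S = values_S,
         stimulus = stimulus, fixed = fixed,
         parameter_names = pn),
    class = "param_set"
  )
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set> stimulus:",
      if (length(x$stimulus)) paste(x$stimulus, collapse = ", ") else "none",
      "| fixed:",
      if (length(x$fixed)) paste(x$fixed, collapse = ", ") else "none", "\n")
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname parameter_set
#' @param x A `param_set`.
#' @param ... Unused.
#' @export
tidy.param_set <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter_names,
    pre_stimulus = unname(x$values_U),
    post_stimulus = unname(x$values_S),
    stimulus = x$parameter_names %in% x$stimulus,
    fixed = x$parameter_names %in% x$fixed
  )
}

#' Names of the free (sampled) parameters
#'
#' @param params A `param_set`.
#' @return Character vector in the documented sampling order (stimulus
#'   parameters appear as `<name>_U`, `<name>_S`).
#' @export
free_names <- function(params) {
  out <- character(0)
  for (nm in params$parameter_names) {
    if (nm %in% params$fixed) next
    if (nm %in% params$stimulus) {
      out <- c(out, paste0(nm, "_U"), paste0(nm, "_S"))
    } else {
      out <- c(out, nm)
    }
  }
  out
}

#' Number of free parameters
#'
#' @param params A `param_set`.
#' @return Integer free-parameter count `m`.
#' @export
n_free <- function(params) length(free_names(params))

#' Extract the free-parameter vector
#'
#' @param params A `param_set`.
#' @return Named numeric vector in [free_names()] order.
#' @export
free_values <- function(params) {
  fn <- free_names(params)
  vapply(fn, function(nm) {
    if (endsWith(nm, "_S")) {
      params$values_S[[sub("_S$", "", nm)]]
    } else if (endsWith(nm, "_U") &&
               sub("_U$", "", nm) %in% params$stimulus) {
      params$values_U[[sub("_U$", "", nm)]]
    } else {
      params$values_U[[nm]]
    }
  }, numeric(1))
}

#' Replace the free-parameter vector
#'
#' @param params A `param_set`.
#' @param x Numeric vector in [free_names()] order.
#' @return The updated `param_set` (non-stimulus values are written to both
#'   the pre- and post-stimulus vectors).
#' @export
set_free_values <- function(params, x) {
  fn <- free_names(params)
  stopifnot(length(x) == length(fn))
  for (k in seq_along(fn)) {
    nm <- fn[k]
    if (endsWith(nm, "_S") && sub("_S$", "", nm) %in% params$stimulus) {
      params$values_S[[sub("_S$", "", nm)]] <- x[k]
    } else if (endsWith(nm, "_U") && sub("_U$", "", nm) %in% params$stimulus) {
      params$values_U[[sub("_U$", "", nm)]] <- x[k]
    } else {
      params$values_U[[nm]] <- x[k]
      params$values_S[[nm]] <- x[k]
    }
  }
  params
}

# Base model parameter behind each free-vector entry ("k1_S" -> "k1").
base_param <- function(free_name) sub("_(U|S)$", "", free_name)

#' Candidate parameter-stimulus hypotheses
#'
#' Builds one [parameter_set()] per stimulus hypothesis (which parameters
#' change value at induction), all sharing the same pre-stimulus values and
#' fixed parameters — the input to a model-selection sweep. The default
#' list covers the six standard single- and multi-parameter hypotheses for
#' the two-state model.
#'
#' @param unstimulated Named numeric vector of pre-stimulus values.
#' @param stimuli List of character vectors naming the stimulus-affected
#'   parameters of each candidate.
#' @param fixed Parameters held fixed during inference.
#' @param model A `gene_model`.
#' @return Named list of `param_set` templates (names like `"k1+mu1"`).
#' @export
stimulus_templates <- function(unstimulated,
                               stimuli = list("k1", "k0", "mu1",
                                              c("k1", "mu1"),
                                              c("k0", "mu1"),
                                              c("k1", "k0", "mu1")),
                               fixed = "delta",
                               model = two_state_model(2)) {
  out <- lapply(stimuli, function(st) {
    parameter_set(unstimulated = unstimulated,
                  stimulated = unstimulated[st],
                  fixed = fixed, model = model)
  })
  names(out) <- vapply(stimuli, paste, character(1), collapse = "+")
  out
}
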