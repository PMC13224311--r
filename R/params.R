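# Canonical parameter order of the three-population model.
.PARAM_NAMES <- c("Te", "Ti", "He", "Hi", "G1", "G2", "G3", "G4", "G5",
                  "R1", "R2", "Di", "input_gain", "noise_exponent", "obs_gain")

.DEFAULT_SCALES <- c(
  Te = 0.004, Ti = 0.016,          # synaptic time constants [s]
  He = 8, Hi = 32,                 # maximal PSP amplitudes [mV]
  G1 = 128, G2 = 102.4, G3 = 64, G4 = 64, G5 = 32,  # intrinsic gains
  R1 = 0.5, R2 = 3,                # sigmoid slope [1/mV] and threshold [mV]
  Di = 0.01,                       # intrinsic conduction delay [s]
  input_gain = 1, noise_exponent = 1, obs_gain = 1
)

# "Standard" prior variances (log scale); all below the unit variance used by
# the dynamics-informed priors.
.DEFAULT_PRIOR_VAR <- c(
  Te = 1/16, Ti = 1/16, He = 1/64, Hi = 1/64,
  G1 = 1/16, G2 = 1/16, G3 = 1/16, G4 = 1/16, G5 = 1/16,
  R1 = 1/16, R2 = 1/16, Di = 1/32,
  input_gain = 1/16, noise_exponent = 1/64, obs_gain = 1/64
)

.DEFAULT_FREE <- c(
  Te = TRUE, Ti = TRUE, He = TRUE, Hi = TRUE,
  G1 = TRUE, G2 = TRUE, G3 = TRUE, G4 = TRUE, G5 = TRUE,
  R1 = TRUE, R2 = TRUE, Di = TRUE,
  input_gain = TRUE, noise_exponent = FALSE, obs_gain = FALSE
)

#' Neural mass model parameter vector
#'
#' Constructs the named log-scale parameter set of the three-population
#' cortical column model (spiny stellate, inhibitory interneuron, pyramidal).
#' Physical values are `scales * exp(theta_log)`, guaranteeing positivity:
#' time constants `Te`, `Ti` and the conduction delay `Di` in seconds,
#' synaptic amplitudes `He`, `Hi` in millivolts, and dimensionless intrinsic
#' gains `G1`--`G5`, sigmoid slope/threshold `R1`, `R2` and
#' observation/innovation parameters.
#'
#' @param theta_log numeric vector of log-scale values, recycled or named;
#'   defaults to zero (physical values equal the scale factors).
#' @param scales positive physical scale factors, one per parameter.
#' @param free_mask logical vector marking estimable entries.
#' @return An object of class `nmm_params`.
#' @examples
#' p <- nmm_params()
#' to_physical(p)[["Te"]]   # 0.004 s
#' @export
nmm_params <- function(theta_log = 0, scales = .DEFAULT_SCALES,
                       free_mask = .DEFAULT_FREE) {
  nm <- .PARAM_NAMES
  th <- rep_len(0, length(nm))
  names(th) <- nm
  if (!is.null(names(theta_log))) {
    bad <- setdiff(names(theta_log), nm)
    if (length(bad)) stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    th[names(theta_log)] <- theta_log
  } else {
    th[] <- rep_len(theta_log, length(nm))
  }
  sc <- rep_len(NA_real_, length(nm)); names(sc) <- nm
  sc[] <- .DEFAULT_SCALES
  if (!is.null(names(scales))) sc[names(scales)] <- scales else sc[] <- scales
  fm <- .DEFAULT_FREE
  if (!is.null(names(free_mask))) fm[names(free_mask)] <- free_mask else fm[] <- rep_len(free_mask, length(nm))
  stopifnot(all(is.finite(sc)), all(sc > 0))
  structure(list(names = nm, theta_log = th, scales = sc,
                 free_mask = fm),
            class = "nmm_params")
}

#' @export
print.nmm_params <- function(x, ...) {
  cat("<nmm_params>", sum(x$free_mask), "free /", length(x$names), "parameters\n")
  print(round(rbind(theta_log = x$theta_log, physical = to_physical(x)), 4))
  invisible(x)
}

#' Replace log-scale values of a parameter set
#'
#' @param params an [nmm_params()] object.
#' @param theta_log named subset (or full unnamed vector) of log-scale values.
#' @return A new `nmm_params` with the values replaced.
#' @export
set_theta <- function(params, theta_log) {
  if (!is.null(names(theta_log))) {
    params$theta_log[names(theta_log)] <- theta_log
  } else {
    stopifnot(length(theta_log) == length(params$theta_log))
    params$theta_log[] <- theta_log
  }
  params
}

#' Map log-scale parameters to physical units
#'
#' @param params an [nmm_params()] object.
#' @return Named numeric vector `scales * exp(theta_log)`, strictly positive.
#' @export
to_physical <- function(params) {
  stopifnot(inherits(params, "nmm_params"))
  if (any(!is.finite(params$theta_log))) {
    bad <- params$names[!is.finite(params$theta_log)]
    stop("non-finite theta_log entry for: ", paste(bad, collapse = ", "))
  }
  params$scales * exp(params$theta_log)
}

#' Closed parameter bounds (log scale)
#'
#' @param lower,upper numeric vectors (length 1 or one per parameter), finite,
#'   with `lower < upper` elementwise.
#' @param names parameter names the bounds align to.
#' @return An object of class `param_bounds`.
#' @export
param_bounds <- function(lower = -1, upper = 0.85, names = .PARAM_NAMES) {
  lo <- rep_len(lower, length(names)); hi <- rep_len(upper, length(names))
  names(lo) <- names(hi) <- names
  stopifnot(all(is.finite(lo)), all(is.finite(hi)), all(lo < hi))
  structure(list(lower = lo, upper = hi, names = names), class = "param_bounds")
}

#' Default search bounds
#'
#' Closed log-scale intervals `[-1, 0.85]` per parameter, covering the
#' biologically plausible span scanned in the free-energy profile preset.
#' @return A `param_bounds` object.
#' @export
default_bounds <- function() param_bounds()

#' Default parameter table
#'
#' One row per parameter: physical scale factor, standard prior mean and
#' variance (log scale), and search bounds. This is the editable table behind
#' [standard_priors()] and [default_bounds()].
#' @return A data.frame with columns name, scale, prior_mean, prior_variance,
#'   lower, upper.
#' @export
default_param_table <- function() {
  data.frame(name = .PARAM_NAMES,
             scale = unname(.DEFAULT_SCALES),
             prior_mean = 0,
             prior_variance = unname(.DEFAULT_PRIOR_VAR),
             lower = -1, upper = 0.85,
             stringsAsFactors = FALSE)
}

#' Read / write a parameter table
#'
#' Flat whitespace/tab-delimited text, one parameter per line with a header:
#' `name scale prior_mean prior_variance lower upper`.
#' @param path file path.
#' @return `read_param_table`: the table as a data.frame.
#' @export
read_param_table <- function(path) {
  tab <- tryCatch(utils::read.table(path, header = TRUE, stringsAsFactors = FALSE),
                  error = function(e) stop("malformed parameter table '", path, "': ",
                                           conditionMessage(e)))
  need <- c("name", "scale", "prior_mean", "prior_variance", "lower", "upper")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("parameter table '", path, "' missing column(s): ",
                         paste(miss, collapse = ", "))
  num <- tab[need[-1]]
  if (any(!vapply(num, is.numeric, TRUE)) || any(!is.finite(as.matrix(num))))
    stop("parameter table '", path, "' has non-numeric or non-finite entries")
  if (any(tab$prior_variance <= 0)) stop("prior variances must be strictly positive")
  if (any(tab$scale <= 0)) stop("scale factors must be strictly positive")
  tab
}

#' @rdname read_param_table
#' @param table a data.frame as returned by [default_param_table()].
#' @export
write_param_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standard Gaussian priors
#'
#' The default prior over log-scale parameters: zero means and the
#' conventional small variances, read from a parameter table so the whole
#' prior specification stays configurable from file.
#'
#' @param table optional parameter table (data.frame or file path). The
#'   shipped default lives at
#'   `system.file("extdata", "standard_priors.tsv", package = "dipdcm")`.
#' @return A `gaussian_belief` of kind `"prior"`.
#' @export
standard_priors <- function(table = NULL) {
  if (is.null(table)) table <- default_param_table()
  if (is.character(table)) table <- read_param_table(table)
  gaussian_belief(mean = stats::setNames(table$prior_mean, table$name),
                  var = stats::setNames(table$prior_variance, table$name),
                  kind = "prior")
}
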