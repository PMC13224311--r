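# File plumbing: spectrum CSV, belief/mixture JSON, estimate tables, and the
# YAML run configuration. All parsing is locale-independent (C numeric
# format) and validates with line-numbered messages.

#' Read and write spectrum files
#'
#' Delimited text with header `freq_hz,log_psd`; metadata is serialised to a
#' JSON sidecar (`<path>.meta.json`) when present. Round trips are identity
#' within 1e-12 on numeric fields.
#'
#' @param path file path.
#' @return `read_spectrum`: a [spectral_observation()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty spectrum file: ", path)
  hdr <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (!identical(hdr, c("freq_hz", "log_psd")))
    stop("spectrum file must have header 'freq_hz,log_psd' (got '", lines[1L], "')")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  for (i in seq_along(parts))
    if (length(parts[[i]]) != 2L)
      stop("row ", i + 1L, " of ", path, " does not have 2 fields")
  f <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  lp <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (any(is.na(f)) || any(is.na(lp))) {
    bad <- which(is.na(f) | is.na(lp))[1L]
    stop("non-numeric value at row ", bad + 1L, " of ", path)
  }
  if (any(!is.finite(f)) || any(!is.finite(lp))) {
    bad <- which(!is.finite(f) | !is.finite(lp))[1L]
    stop("non-finite value at row ", bad + 1L, " of ", path)
  }
  dec <- which(diff(f) <= 0)
  if (length(dec))
    stop("frequencies not strictly increasing at row ", dec[1L] + 2L, " of ", path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::fromJSON(meta_path, simplifyVector = TRUE) else NULL
  obs <- spectral_observation(f, lp,
    source = if (!is.null(meta$source)) meta$source else "empirical",
    normalised = isTRUE(meta$normalised),
    band = if (!is.null(meta$band)) meta$band else range(f))
  obs
}

#' @rdname read_spectrum
#' @param obs a [spectral_observation()].
#' @export
write_spectrum <- function(obs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("freq_hz,log_psd", con)
  writeLines(paste(format(obs$freqs, digits = 17, trim = TRUE, scientific = FALSE),
                   format(obs$log_psd, digits = 17, trim = TRUE),
                   sep = ","), con)
  jsonlite::write_json(list(source = obs$meta$source,
                            normalised = obs$meta$normalised,
                            band = obs$meta$band),
                       paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write Gaussian beliefs (JSON)
#'
#' Schema: `{names, mean, variance, free_energy, converged, n_iter}`.
#' @param path file path.
#' @return `read_belief`: a [gaussian_belief()].
#' @export
read_belief <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("names", "mean", "variance", "kind")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("belief file ", path, " missing field(s): ",
                         paste(miss, collapse = ", "))
  gaussian_belief(stats::setNames(x$mean, x$names),
                  stats::setNames(x$variance, x$names),
                  kind = x$kind,
                  free_energy = x$free_energy)
}

#' @rdname read_belief
#' @param b a [gaussian_belief()].
#' @export
write_belief <- function(b, path) {
  jsonlite::write_json(list(names = names(b$mean), mean = unname(b$mean),
                            variance = unname(b$var), kind = b$kind,
                            free_energy = b$free_energy),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read and write posterior mixtures (JSON)
#'
#' Schema: `{names, m, components: [{mean, variance, free_energy}]}`.
#' @param path file path.
#' @return `read_mixture`: a `posterior_mixture`.
#' @export
read_mixture <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(x$names) || is.null(x$components))
    stop("mixture file ", path, " missing 'names' or 'components'")
  nm <- unlist(x$names)
  comps <- lapply(x$components, function(cc)
    gaussian_belief(stats::setNames(unlist(cc$mean), nm),
                    stats::setNames(unlist(cc$variance), nm),
                    kind = "posterior",
                    free_energy = if (is.null(cc$free_energy)) NULL
                                  else cc$free_energy))
  average_posteriors(comps)
}

#' @rdname read_mixture
#' @param mix a `posterior_mixture`.
#' @export
write_mixture <- function(mix, path) {
  jsonlite::write_json(
    list(names = mix$names, m = length(mix$components),
         components = lapply(mix$components, function(p)
           list(mean = unname(p$mean), variance = unname(p$var),
                free_energy = p$free_energy))),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read and write GA estimate tables (CSV)
#'
#' One row per realisation: `seed`, the log-parameter columns, `J1`, `J2`,
#' `rmse`.
#' @param path file path.
#' @return `read_estimates`: a `ga_estimates` data.frame.
#' @export
read_estimates <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("seed", "J1", "J2", "rmse")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("estimate table ", path, " missing column(s): ",
                         paste(miss, collapse = ", "))
  class(tab) <- c("ga_estimates", "data.frame")
  tab
}

#' @rdname read_estimates
#' @param estimates a `ga_estimates` data.frame.
#' @export
write_estimates <- function(estimates, path) {
  df <- as.data.frame(estimates)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Accepts the embedded parameter table (list of per-parameter entries with
#' `name, scale, prior_mean, prior_variance, lower, upper`) plus any of the
#' run settings (`bands`, `n`, `m`, `generations`, `pop_size`, `seed`).
#'
#' @param path YAML file path.
#' @return Named list of settings; `$param_table` is a data.frame when
#'   present.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$parameters)) {
    cfg$param_table <- do.call(rbind, lapply(cfg$parameters, as.data.frame))
    cfg$parameters <- NULL
  }
  cfg
}
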