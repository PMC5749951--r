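#' Observable projection models
#'
#' An `observable_model` maps state occupancies to the (relative, unitless)
#' signal an experiment records: a per-species weight vector plus a baseline.
#' Amplitudes are free fit parameters downstream, so only the ordering of the
#' weights carries meaning.
#'
#' Default weight tables per reporter:
#' \describe{
#'   \item{mant_fluorescence}{all mant-nucleotide-bound myosin states weigh 1
#'     (bound mant fluoresces, free mant does not).}
#'   \item{pyrene_actin}{free actin and weakly attached states weigh 1, the
#'     strongly bound (rigor-like) AM and AM.ADP states 0 — pyrene
#'     fluorescence is quenched by strong binding.}
#'   \item{tryptophan}{post-hydrolysis M.ADP.Pi weighs 1, M.ATP 0.5: the
#'     conserved relay-loop tryptophan reports the switch-2-coupled converter
#'     priming that follows ATP binding and hydrolysis.}
#'   \item{light_scattering}{all actin-attached states weigh 1 (attached mass
#'     scatters).}
#'   \item{nadh_atpase}{the free ADP pool weighs 1; the NADH-coupled assay is
#'     modeled as accumulated ADP production, whose slope is the steady-state
#'     rate, not as the full coupled-enzyme cascade.}
#' }
#'
#' @param kind Reporter kind, one of the names above, or `"custom"`.
#' @param weights Named numeric vector of per-species weights; unnamed species
#'   default to 0. Required for `kind = "custom"`, optional override otherwise.
#' @param baseline Baseline offset added to the projected signal.
#' @return An object of class `observable_model`.
#' @export
observable_model <- function(kind = c("mant_fluorescence", "pyrene_actin",
                                      "tryptophan", "light_scattering",
                                      "nadh_atpase", "custom"),
                             weights = NULL, baseline = 0) {
  kind <- match.arg(kind)
  w <- stats::setNames(numeric(length(ALL_SPECIES)), ALL_SPECIES)
  defaults <- switch(kind,
    mant_fluorescence = c(M.ATP = 1, M.ADP.Pi = 1, M.ADP = 1,
                          AM.ATP = 1, AM.ADP.Pi = 1, AM.ADP = 1),
    pyrene_actin = c(A = 1, AM.ATP = 1, AM.ADP.Pi = 1, AM = 0, AM.ADP = 0),
    tryptophan = c(M.ADP.Pi = 1, M.ATP = 0.5),
    light_scattering = c(AM = 1, AM.ATP = 1, AM.ADP.Pi = 1, AM.ADP = 1),
    nadh_atpase = c(ADP = 1),
    custom = NULL
  )
  if (!is.null(defaults)) w[names(defaults)] <- defaults
  if (!is.null(weights)) {
    unknown <- setdiff(names(weights), ALL_SPECIES)
    if (length(unknown)) stop("unknown species in weights: ",
                              paste(unknown, collapse = ", "))
    w[names(weights)] <- weights
  } else if (kind == "custom") {
    stop("custom observable models require an explicit `weights` vector")
  }
  if (any(!is.finite(w)) || !is.finite(baseline)) {
    stop("weights and baseline must be finite")
  }
  structure(list(kind = kind, weights = w, baseline = baseline),
            class = "observable_model")
}

#' Project a state trajectory onto an experimental signal
#'
#' Computes `signal(t) = baseline + sum_s weight_s * occupancy_s(t)` for every
#' time point of an [simulate_cycle()] trajectory. Linear by construction:
#' projecting a linear combination of trajectories equals the same linear
#' combination of projected signals (zero baseline).
#'
#' @param traj An `occupancy_trajectory`.
#' @param model An [observable_model()] covering every species in `traj`.
#' @return A `signal_trace`: data.frame with columns `time` and `signal`,
#'   carrying the observable kind and conditions as attributes.
#' @export
project_signal <- function(traj, model) {
  stopifnot(inherits(model, "observable_model"))
  species <- setdiff(colnames(traj), "time")
  unknown <- setdiff(species, names(model$weights))
  if (length(unknown)) {
    stop("species without a weight in the observable model: ",
         paste(unknown, collapse = ", "))
  }
  sig <- model$baseline +
    as.matrix(traj[, species, drop = FALSE]) %*% model$weights[species]
  signal_trace(traj$time, as.numeric(sig), observable = model$kind,
               conditions = attr(traj, "conditions"))
}

#' Construct a time-stamped signal trace
#'
#' @param time,signal Numeric vectors of equal length.
#' @param observable Reporter kind label.
#' @param conditions Optional [ligand_conditions()] metadata.
#' @param truth Optional named list of generating ground-truth parameters
#'   (filled by the synthetic-data generators).
#' @return A `signal_trace` data.frame.
#' @export
signal_trace <- function(time, signal, observable = "custom",
                         conditions = NULL, truth = NULL) {
  stopifnot(length(time) == length(signal))
  structure(data.frame(time = time, signal = signal),
            class = c("signal_trace", "data.frame"),
            observable = observable, conditions = conditions, truth = truth)
}

#' Read / write signal traces as two-column delimited text
#'
#' Traces are stored as tab-separated `time`, `signal` columns. Metadata
#' (observable kind and ground-truth parameters, when present) is carried in
#' `# key: value` comment lines so fixture files are self-describing.
#'
#' @param trace A `signal_trace`.
#' @param path File path.
#' @return `read_trace` returns a `signal_trace`; `write_trace` the path.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# observable: ", attr(trace, "observable")), con)
  tr <- attr(trace, "truth")
  if (!is.null(tr)) {
    for (nm in names(tr)) {
      writeLines(sprintf("# truth.%s: %s", nm,
                         paste(format(tr[[nm]], digits = 15), collapse = ",")),
                 con)
    }
  }
  utils::write.table(data.frame(time = trace$time, signal = trace$signal),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                            sep = "\t")
  observable <- sub("^# observable: ", "",
                    grep("^# observable:", hdr, value = TRUE)[1])
  truth_lines <- grep("^# truth\\.", hdr, value = TRUE)
  truth <- NULL
  if (length(truth_lines)) {
    keys <- sub("^# truth\\.([^:]+):.*$", "\\1", truth_lines)
    vals <- sub("^# truth\\.[^:]+: ", "", truth_lines)
    truth <- stats::setNames(
      lapply(vals, function(v) {
        x <- strsplit(v, ",")[[1]]
        n <- suppressWarnings(as.numeric(x))
        if (any(is.na(n))) x else n
      }), keys)
  }
  signal_trace(body$time, body$signal,
               observable = if (is.na(observable)) "custom" else observable,
               truth = truth)
}
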