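#' @include AllClasses.R
NULL

#' Convert model parameters to and from a flat list
#'
#' @param params A [ConeModelParams-class] object.
#' @return `paramsToList()`: named list with one entry per slot, keys equal
#'   to the slot names.
#' @examples
#' str(paramsToList(ConeModelParams()))
#' @export
paramsToList <- function(params) {
  stopifnot(is(params, "ConeModelParams"))
  setNames(lapply(slotNames(params), function(s) slot(params, s)),
           slotNames(params))
}

#' @rdname paramsToList
#' @param x Named list (e.g. parsed from YAML/JSON) with a subset of the
#'   parameter fields; unknown keys are rejected.
#' @param defaults Parameter object supplying unspecified fields.
#' @return `paramsFromList()`: a [ConeModelParams-class] object.
#' @export
paramsFromList <- function(x, defaults = ConeModelParams()) {
  stopifnot(is.list(x))
  known <- slotNames(defaults)
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  p <- defaults
  for (nm in names(x)) {
    v <- x[[nm]]
    if (nm == "dio3_in_immature_cones") v <- as.logical(v)
    else v <- as.numeric(v)
    slot(p, nm) <- v
  }
  validObject(p)
  p
}

#' Read and write model parameters as YAML
#'
#' Flat YAML with keys exactly matching the [ConeModelParams-class] field
#' names (a JSON-compatible subset). Unknown keys are rejected on read.
#'
#' @param params A [ConeModelParams-class] object.
#' @param path File path.
#' @return `writeModelParams()` returns `path` invisibly;
#'   `readModelParams()` returns a [ConeModelParams-class] object.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeModelParams(ConeModelParams(mutant_degradation_fraction = 0.06), f)
#' readModelParams(f)
#' @export
writeModelParams <- function(params, path) {
  yaml::write_yaml(paramsToList(params), path)
  invisible(path)
}

#' @rdname writeModelParams
#' @export
readModelParams <- function(path, defaults = ConeModelParams()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- yaml::read_yaml(path)
  if (is.null(x)) x <- list()
  paramsFromList(x, defaults)
}

#' @rdname writeModelParams
#' @inheritParams paramsFromList
NULL

#' Write a trajectory as tidy TSV
#'
#' One row per (snapshot, class) with columns `time`, `class`, `count`,
#' `T3`, `seed`, `condition`.
#'
#' @param trajectory A [Trajectory-class] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @examples
#' tr <- simulateOrganoid(ConeModelParams(), initial_rpc = 200, seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' writeTrajectoryTSV(tr, f)
#' head(read.delim(f))
#' @export
writeTrajectoryTSV <- function(trajectory, path) {
  stopifnot(is(trajectory, "Trajectory"))
  sn <- trajectory@snapshots
  long <- do.call(rbind, lapply(cellClasses(), function(cl)
    data.frame(time = sn$time, class = cl, count = sn[[cl]], T3 = sn$T3,
               seed = trajectory@seed, condition = trajectory@condition,
               stringsAsFactors = FALSE)))
  long <- long[order(long$time, match(long$class, cellClasses())), ]
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tidy trajectory TSV back into a snapshot table
#'
#' Inverse of [writeTrajectoryTSV()] up to the wide snapshot table (the
#' parameter object is not serialised in the TSV).
#'
#' @param path TSV file written by [writeTrajectoryTSV()].
#' @return data.frame with `time`, one column per class, and `T3`.
#' @export
readTrajectoryTSV <- function(path) {
  long <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("time", "class", "count", "T3")
  if (!all(need %in% names(long)))
    stop("not a trajectory TSV: need columns ", paste(need, collapse = ", "))
  times <- sort(unique(long$time))
  wide <- data.frame(time = times)
  for (cl in cellClasses()) {
    d <- long[long$class == cl, ]
    wide[[cl]] <- d$count[match(times, d$time)]
  }
  wide$T3 <- long$T3[match(times, long$time)]
  wide
}

#' Write replicate-level experiment results
#'
#' Writes the per-replicate table of one or two [ExperimentResult-class]
#' objects as TSV (with a `model` column) and a JSON summary with the CVs,
#' means and seeds.
#'
#' @param results List of [ExperimentResult-class] objects (e.g. the pair
#'   from [noiseFilterExperiment()]).
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisible list of written paths.
#' @export
writeExperimentResults <- function(results, tsv_path = NULL,
                                   json_path = NULL) {
  results <- Filter(function(x) is(x, "ExperimentResult"), results)
  if (!length(results)) stop("no ExperimentResult objects supplied")
  if (!is.null(tsv_path)) {
    tab <- do.call(rbind, lapply(results, function(r)
      cbind(data.frame(model = r@model), replicateCounts(r))))
    write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    summ <- lapply(results, function(r) {
      s <- summaryStats(r)
      list(model = r@model, condition = r@condition, n = s$n,
           mean_total_pr = s$mean, sd_total_pr = s$sd, cv = s$cv,
           seed = r@seed)
    })
    names(summ) <- vapply(results, function(r) r@model, character(1))
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(tsv = tsv_path, json = json_path))
}

#' Write an observation table as tidy TSV with a JSON metadata sidecar
#'
#' @param table An [ObservationTable-class] object.
#' @param tsv_path Output TSV path; the JSON sidecar is written next to it
#'   as `<tsv_path>.meta.json`.
#' @return Invisible list of written paths.
#' @export
writeObservationTSV <- function(table, tsv_path) {
  stopifnot(is(table, "ObservationTable"))
  write.table(table@observations, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(scale = table@scale, noise_cv = table@noise_cv,
               rho_fraction = table@rho_fraction, seed = table@seed)
  meta_path <- paste0(tsv_path, ".meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(tsv = tsv_path, meta = meta_path))
}
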