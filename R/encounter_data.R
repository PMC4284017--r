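#' Study calendar
#'
#' Defines the annual sampling design: the label of the first breeding season
#' and the number of annual occasions.  Occasions are 1-based and consecutive;
#' "interval t" denotes survival from occasion t to t + 1.
#'
#' @param first_season Year label of occasion 1 (e.g. 2003).
#' @param n_occasions Number of annual sampling occasions (>= 2).
#' @return An object of class \code{study_calendar}.
#' @examples
#' study_calendar(2003, 10)
#' @export
study_calendar <- function(first_season = 2003L, n_occasions = 10L) {
  n_occasions <- as.integer(n_occasions)
  if (is.na(n_occasions) || n_occasions < 2L)
    stop("n_occasions must be an integer >= 2")
  structure(list(first_season = as.integer(first_season),
                 n_occasions = n_occasions),
            class = "study_calendar")
}

#' @export
print.study_calendar <- function(x, ...) {
  cat(sprintf("Study calendar: %d annual occasions, seasons %d-%d\n",
              x$n_occasions, x$first_season,
              x$first_season + x$n_occasions - 1L))
  invisible(x)
}

#' Seasons covered by a calendar
#' @param calendar A \code{study_calendar}.
#' @return Integer vector of season labels, one per occasion.
#' @export
seasons <- function(calendar) {
  calendar$first_season + seq_len(calendar$n_occasions) - 1L
}

#' Capture-mark-recapture dataset
#'
#' Bundles encounter histories, the study calendar, the annual covariate
#' table and the pooled fledging-mass standardizer into a validated dataset.
#'
#' Each animal is a row of \code{histories} plus a row of the 0/1 detection
#' matrix.  Fledgling-marked animals enter the unobservable pre-return state
#' at tagging; adult-marked animals enter the observable state.  Marking is
#' the first detection: \code{detections[i, mark_occasion[i]] == 1} and all
#' earlier entries are 0.
#'
#' @param calendar A \code{study_calendar}.
#' @param histories \code{data.frame} with columns \code{animal_id},
#'   \code{mark_occasion}, \code{mark_class} ("fledgling" or "adult") and
#'   \code{mass} (kg at tagging; \code{NA} for adults or when unrecorded).
#' @param detections Integer 0/1 matrix, one row per animal, one column per
#'   occasion.
#' @param year_covariates Optional \code{data.frame} of annual covariates
#'   (see \code{\link{read_year_covariates}}), or \code{NULL}.
#' @return An object of class \code{cmr_dataset}.
#' @export
cmr_dataset <- function(calendar, histories, detections,
                        year_covariates = NULL) {
  stopifnot(inherits(calendar, "study_calendar"))
  histories <- as.data.frame(histories, stringsAsFactors = FALSE)
  req <- c("animal_id", "mark_occasion", "mark_class", "mass")
  if (!all(req %in% names(histories)))
    stop("histories must have columns: ", paste(req, collapse = ", "))
  histories$animal_id <- as.character(histories$animal_id)
  histories$mark_occasion <- as.integer(histories$mark_occasion)
  detections <- as.matrix(detections)
  storage.mode(detections) <- "integer"
  x <- structure(list(calendar = calendar,
                      histories = histories,
                      detections = detections,
                      year_covariates = year_covariates,
                      mass_standardizer = NULL),
                 class = "cmr_dataset")
  validate_dataset(x)
  x$mass_standardizer <- .mass_standardizer(x)
  x
}

.mass_standardizer <- function(dataset) {
  m <- dataset$histories$mass[dataset$histories$mark_class == "fledgling"]
  m <- m[!is.na(m)]
  if (length(m) >= 2L && stats::sd(m) > 0) standardize(m) else NULL
}

#' Validate a cmr_dataset
#'
#' Checks structural invariants: history length equals the calendar length,
#' no duplicate animal ids, marking is the first detection, detections are
#' 0/1, mark classes are known, and masses are nonnegative.
#'
#' @param dataset A \code{cmr_dataset}.
#' @return The dataset, invisibly; errors describe the first offending animal.
#' @export
validate_dataset <- function(dataset) {
  cal <- dataset$calendar
  h <- dataset$histories
  d <- dataset$detections
  n <- nrow(h)
  if (nrow(d) != n)
    stop("detections has ", nrow(d), " rows but histories has ", n)
  if (n > 0 && ncol(d) != cal$n_occasions)
    stop("detection matrix has ", ncol(d), " columns; calendar has ",
         cal$n_occasions, " occasions")
  if (anyDuplicated(h$animal_id))
    stop("duplicate animal_id: ",
         h$animal_id[duplicated(h$animal_id)][1L])
  if (n == 0L) return(invisible(dataset))
  if (!all(d %in% c(0L, 1L)))
    stop("detections must be 0/1")
  if (!all(h$mark_class %in% c("fledgling", "adult")))
    stop("mark_class must be 'fledgling' or 'adult'")
  if (any(h$mark_occasion < 1L | h$mark_occasion > cal$n_occasions))
    stop("mark_occasion outside calendar")
  for (i in seq_len(n)) {
    m <- h$mark_occasion[i]
    if (d[i, m] != 1L)
      stop("animal ", h$animal_id[i], ": no detection at marking occasion")
    if (m > 1L && any(d[i, seq_len(m - 1L)] != 0L))
      stop("animal ", h$animal_id[i], ": detection before marking")
  }
  bad_mass <- !is.na(h$mass) & h$mass < 0
  if (any(bad_mass))
    stop("negative mass for animal ", h$animal_id[bad_mass][1L])
  if (any(!is.na(h$mass) & h$mark_class == "adult"))
    stop("mass recorded for adult-marked animal (fledging mass is a ",
         "fledgling-only covariate)")
  invisible(dataset)
}

#' @export
print.cmr_dataset <- function(x, ...) {
  h <- x$histories
  cat(sprintf("cmr_dataset: %d animals over %d occasions (%d-%d)\n",
              nrow(h), x$calendar$n_occasions, x$calendar$first_season,
              x$calendar$first_season + x$calendar$n_occasions - 1L))
  cat(sprintf("  fledgling-marked: %d (%d with mass)  adult-marked: %d\n",
              sum(h$mark_class == "fledgling"),
              sum(h$mark_class == "fledgling" & !is.na(h$mass)),
              sum(h$mark_class == "adult")))
  cat(sprintf("  annual covariates: %s\n",
              if (is.null(x$year_covariates)) "none"
              else paste(setdiff(names(x$year_covariates), "season"),
                         collapse = ", ")))
  invisible(x)
}

#' Number of animals in a dataset
#' @param dataset A \code{cmr_dataset}.
#' @return Integer count of encounter histories.
#' @export
n_animals <- function(dataset) nrow(dataset$histories)

#' Standardize a covariate to zero mean and unit standard deviation
#'
#' Computes the z-score using the sample (n - 1) standard deviation and keeps
#' the centre and scale so effects estimated per standard deviation can be
#' back-transformed to natural units.
#'
#' @param values Numeric vector, length >= 2, with positive spread.
#' @return A \code{standardized_covariate}: list with \code{raw},
#'   \code{center}, \code{scale} and \code{z}.
#' @examples
#' standardize(c(1, 2, 3))$z   # -1 0 1
#' @export
standardize <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values to standardize")
  if (anyNA(values)) stop("values contain NA")
  s <- stats::sd(values)
  if (!is.finite(s) || s <= 0)
    stop("cannot standardize a constant sequence (zero scale)")
  m <- mean(values)
  structure(list(raw = values, center = m, scale = s,
                 z = (values - m) / s),
            class = "standardized_covariate")
}

#' Back-transform standardized values to the raw scale
#' @param std A \code{standardized_covariate}.
#' @param z Standardized values (defaults to the stored sequence).
#' @return Values on the raw scale: \code{center + scale * z}.
#' @export
destandardize <- function(std, z = std$z) std$center + std$scale * z

#' Remove fledglings lacking a fledging mass
#'
#' Fledgling-marked animals without a recorded tagging mass cannot contribute
#' to individual-covariate models and are dropped ahead of analysis (the
#' penguin study removed 11 such birds).  Adult-marked animals are untouched
#' and retained histories are unaltered.  The pooled mass standardizer is
#' recomputed on the retained fledglings.
#'
#' @param dataset A \code{cmr_dataset}.
#' @return List with \code{dataset} (filtered) and \code{removed} (count).
#' @export
filter_missing_mass <- function(dataset) {
  h <- dataset$histories
  drop <- h$mark_class == "fledgling" & is.na(h$mass)
  out <- dataset
  if (any(drop)) {
    out$histories <- h[!drop, , drop = FALSE]
    rownames(out$histories) <- NULL
    out$detections <- dataset$detections[!drop, , drop = FALSE]
    out$mass_standardizer <- .mass_standardizer(out)
  }
  list(dataset = out, removed = sum(drop))
}

#' Read encounter histories from a MARK-dialect .inp file
#'
#' Each record line holds a 0/1 history string of length
#' \code{calendar$n_occasions}, a frequency field (1 here), a group indicator
#' (0 = adult-marked, 1 = fledgling-marked), an optional fledging-mass column
#' (kg) and an optional trailing semicolon.  Lines that are empty or start
#' with \code{/*} are skipped.  The marking occasion is the first '1'.
#'
#' @param path Path to the .inp file.
#' @param calendar A \code{study_calendar}.
#' @param year_covariates Optional annual covariate table to attach.
#' @return A validated \code{cmr_dataset}.
#' @export
read_inp <- function(path, calendar, year_covariates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  T <- calendar$n_occasions
  ids <- character(); marks <- integer(); classes <- character()
  masses <- numeric(); dets <- list()
  rec <- 0L
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[[ln]])
    if (raw == "" || startsWith(raw, "/*")) next
    raw <- sub(";\\s*$", "", raw)
    parts <- strsplit(raw, "\\s+")[[1]]
    if (length(parts) < 3L)
      stop(sprintf("line %d: expected 'history freq group [mass]'", ln))
    hist <- parts[[1]]
    if (nchar(hist) != T)
      stop(sprintf("line %d: history length %d, calendar expects %d",
                   ln, nchar(hist), T))
    digits <- strsplit(hist, "")[[1]]
    if (!all(digits %in% c("0", "1")))
      stop(sprintf("line %d: non-binary character in history", ln))
    det <- as.integer(digits)
    if (sum(det) == 0L)
      stop(sprintf("line %d: all-zero history (no marking occasion)", ln))
    freq <- suppressWarnings(as.integer(parts[[2]]))
    if (is.na(freq) || freq < 1L)
      stop(sprintf("line %d: bad frequency field '%s'", ln, parts[[2]]))
    grp <- parts[[3]]
    if (!grp %in% c("0", "1"))
      stop(sprintf("line %d: group must be 0 (adult) or 1 (fledgling)", ln))
    cls <- if (grp == "1") "fledgling" else "adult"
    mass <- NA_real_
    if (length(parts) >= 4L) {
      mass <- suppressWarnings(as.numeric(parts[[4]]))
      if (is.na(mass))
        stop(sprintf("line %d: non-numeric mass '%s'", ln, parts[[4]]))
      if (cls == "adult")
        stop(sprintf("line %d: mass given for adult-marked animal", ln))
    }
    for (k in seq_len(freq)) {
      rec <- rec + 1L
      ids[rec] <- sprintf("A%05d", rec)
      marks[rec] <- match(1L, det)
      classes[rec] <- cls
      masses[rec] <- mass
      dets[[rec]] <- det
    }
  }
  detections <- if (rec > 0L) do.call(rbind, dets)
                else matrix(integer(), 0L, T)
  cmr_dataset(calendar,
              data.frame(animal_id = ids, mark_occasion = marks,
                         mark_class = classes, mass = masses,
                         stringsAsFactors = FALSE),
              detections, year_covariates)
}

#' Write encounter histories to a MARK-dialect .inp file
#'
#' Emits one record line per animal in the dialect read by
#' \code{\link{read_inp}}, ordered by \code{animal_id}, masses formatted to
#' two decimals.
#'
#' @param dataset A \code{cmr_dataset}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_inp <- function(dataset, path) {
  validate_dataset(dataset)
  h <- dataset$histories
  ord <- order(h$animal_id)
  lines <- character(nrow(h))
  for (j in seq_along(ord)) {
    i <- ord[j]
    hist <- paste(dataset$detections[i, ], collapse = "")
    grp <- if (h$mark_class[i] == "fledgling") "1" else "0"
    mass <- if (!is.na(h$mass[i])) sprintf(" %.2f", h$mass[i]) else ""
    lines[j] <- sprintf("%s 1 %s%s;", hist, grp, mass)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Annual covariate column names understood by the package
#' @return Character vector of canonical covariate column names.
#' @export
year_covariate_names <- function() {
  c("pred_pressure", "lsst_lag0", "lsst_lag1", "enso_lag2", "enso_lag3",
    "sam_lag0", "sam_lag1", "gateway_days", "mean_fledging_mass")
}

#' Read the annual covariate table
#'
#' Reads a CSV with one row per occasion and a \code{season} column used to
#' sort rows into calendar order.  Lags are pre-applied by the data preparer:
#' the value stored at occasion t is the value influencing survival over
#' interval t to t + 1.  Missing optional columns are allowed and recorded in
#' the \code{"missing_covariates"} attribute.
#'
#' @param path CSV path with header
#'   \code{season,pred_pressure,lsst_lag0,lsst_lag1,enso_lag2,enso_lag3,sam_lag0,sam_lag1,gateway_days,mean_fledging_mass}.
#' @param calendar A \code{study_calendar}.
#' @return A \code{data.frame} aligned to occasions 1..n_occasions.
#' @export
read_year_covariates <- function(path, calendar) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) != calendar$n_occasions)
    stop("covariate table has ", nrow(tab), " rows; calendar has ",
         calendar$n_occasions, " occasions")
  if (!"season" %in% names(tab))
    stop("covariate table needs a 'season' column")
  want <- seasons(calendar)
  if (!setequal(tab$season, want))
    stop("covariate seasons do not match the calendar (",
         paste(want, collapse = ", "), ")")
  tab <- tab[match(want, tab$season), , drop = FALSE]
  rownames(tab) <- NULL
  known <- year_covariate_names()
  missing <- setdiff(known, names(tab))
  for (nm in intersect(known, names(tab))) {
    if (!is.numeric(tab[[nm]]))
      stop("non-numeric values in covariate column '", nm, "'")
  }
  attr(tab, "missing_covariates") <- missing
  tab
}

#' Write the annual covariate table
#' @param year_covariates Covariate \code{data.frame} with a season column.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_year_covariates <- function(year_covariates, path) {
  utils::write.csv(year_covariates, path, row.names = FALSE)
  invisible(path)
}

#' Standardized annual covariate values over survival intervals
#'
#' Annual covariates act on survival intervals 1..(n_occasions - 1), so the
#' standardization (z-score, sample sd) is computed over those occasions.
#'
#' @param dataset A \code{cmr_dataset} with a covariate table.
#' @param name Covariate column name.
#' @return A \code{standardized_covariate} over intervals 1..T-1.
#' @export
standardized_year_covariate <- function(dataset, name) {
  yc <- dataset$year_covariates
  if (is.null(yc) || !name %in% names(yc))
    stop("annual covariate '", name, "' not present in dataset")
  T <- dataset$calendar$n_occasions
  vals <- yc[[name]][seq_len(T - 1L)]
  if (anyNA(vals)) stop("annual covariate '", name, "' has missing values")
  standardize(vals)
}
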