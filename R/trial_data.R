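#' Declared factor levels for germination-trial covariates
#'
#' The experimental design manipulated four growing conditions: temperature
#' (constant 25C or 30C, or fluctuating day/night regimes), germination
#' medium, chemical pretreatment of the seed coat, and photoperiod
#' (hours light / hours dark). Every trial-group record must use one of
#' these levels verbatim.
#'
#' @return Named list of character vectors, one per treatment factor.
#' @export
trial_levels <- function() {
  list(
    temperature = c("25C", "30C", "20C/15C", "27C/15C"),
    media       = c("sand", "sand_soil", "growth_media"),
    pretreated  = c("no", "yes"),
    photoperiod = c("15L/9D", "12L/12D", "0L/24D")
  )
}

#' Default reference levels for treatment factors
#'
#' The reference condition is a fluctuating 27C/15C temperature regime,
#' a sand/soil medium, no pretreatment, and a 12 h light / 12 h dark
#' photoperiod. Marginal treatment effects are reported against this
#' profile unless overridden.
#'
#' @return Named character vector mapping factor name to reference level.
#' @export
default_reference_levels <- function() {
  c(temperature = "27C/15C", media = "sand_soil",
    pretreated = "no", photoperiod = "12L/12D")
}

trial_columns <- c("group_id", "n_planted", "n_germinated", "depth_cm",
                   "provenance", "temperature", "media", "pretreated",
                   "photoperiod")

#' Map a depth below the marsh surface to its 2-cm slice index
#'
#' Cores are sectioned into 2-cm slices; a depth is represented by the slice
#' that contains it. Surface (depth 0) material maps to slice 1.
#'
#' @param depth_cm Non-negative numeric vector of depths in cm.
#' @return Integer vector of slice indices (1-based).
#' @export
depth_interval_id <- function(depth_cm) {
  stopifnot(all(depth_cm >= 0))
  pmax(1L, as.integer(ceiling(depth_cm / 2)))
}

#' Validate a table of germination trial groups
#'
#' Checks the structural invariants of the observation unit: counts are
#' non-negative integers with `n_germinated <= n_planted` and
#' `n_planted >= 1`, depths are non-negative, and every treatment value
#' belongs to its declared level set ([trial_levels()]). By default
#' validation is strict (fail fast with the offending row index);
#' `permissive = TRUE` instead drops invalid rows with a warning.
#'
#' @param trials Data frame with the columns listed in [read_trials()].
#' @param permissive Drop invalid rows instead of erroring?
#' @return A validated tibble with an added `depth_interval_id` column,
#'   row order preserved.
#' @export
validate_trials <- function(trials, permissive = FALSE) {
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing) > 0) {
    stop("trials table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  trials <- tibble::as_tibble(trials)
  lv <- trial_levels()

  bad_reason <- rep(NA_character_, nrow(trials))
  note <- function(idx, reason) {
    first <- idx & is.na(bad_reason)
    bad_reason[first] <<- reason
  }
  note(!is.finite(trials$n_planted) | trials$n_planted < 1 |
         trials$n_planted != round(trials$n_planted),
       "n_planted must be a positive integer")
  note(!is.finite(trials$n_germinated) | trials$n_germinated < 0 |
         trials$n_germinated != round(trials$n_germinated),
       "n_germinated must be a non-negative integer")
  note(trials$n_germinated > trials$n_planted,
       "n_germinated exceeds n_planted")
  note(!is.finite(trials$depth_cm) | trials$depth_cm < 0,
       "depth_cm must be non-negative")
  for (f in names(lv)) {
    note(!(as.character(trials[[f]]) %in% lv[[f]]),
         paste0("unknown ", f, " level"))
  }

  bad <- which(!is.na(bad_reason))
  if (length(bad) > 0) {
    msg <- paste0("row ", bad[1], ": ", bad_reason[bad[1]],
                  if (length(bad) > 1) paste0(" (and ", length(bad) - 1,
                                              " more invalid row(s))"))
    if (!permissive) stop("invalid trial data: ", msg, call. = FALSE)
    warning("dropping ", length(bad), " invalid row(s); first: ", msg,
            call. = FALSE)
    trials <- trials[-bad, , drop = FALSE]
  }

  dplyr::mutate(
    trials,
    n_planted = as.integer(.data$n_planted),
    n_germinated = as.integer(.data$n_germinated),
    provenance = as.character(.data$provenance),
    depth_interval_id = depth_interval_id(.data$depth_cm)
  )
}

#' Read germination trial groups from CSV
#'
#' Expects a UTF-8, comma-separated file with header columns
#' `group_id,n_planted,n_germinated,depth_cm,provenance,temperature,media,pretreated,photoperiod`.
#' One row is one group of seeds sharing a depth slice, provenance, and
#' treatment combination.
#'
#' @inheritParams validate_trials
#' @param path Path to the CSV file.
#' @return Validated tibble of trial groups (see [validate_trials()]).
#' @export
read_trials <- function(path, permissive = FALSE) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_trials(raw, permissive = permissive)
}

#' Write germination trial groups to CSV
#'
#' Inverse of [read_trials()]: writes the canonical columns so that a
#' write/read round trip is the identity on all fields.
#'
#' @param trials Validated trial table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials[, trial_columns], path, progress = FALSE)
  invisible(path)
}

#' Load the packaged decade-by-location seed count table
#'
#' The package ships a transcription of the study-wide summary of seeds
#' planted (and, in parentheses in the original, germinated) per collection
#' decade and source location: ten marsh locations plus greenhouse-grown
#' modern accessions. The loader re-checks the transcription against the
#' printed marginal totals (per-location totals and the 10,588-seed grand
#' total) and errors on any mismatch.
#'
#' @return Tibble with columns `decade`, `location`, `planted`, `germinated`.
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "table2.csv", package = "marshseed",
                      mustWork = TRUE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         decade = readr::col_integer(),
                         location = readr::col_character(),
                         planted = readr::col_integer(),
                         germinated = readr::col_integer()
                       ))
  expected <- c(`1` = 3644L, `2` = 2871L, `3` = 208L, `4` = 201L, `5` = 4L,
                `6` = 18L, `7` = 2503L, `8` = 10L, `9` = 23L, `10` = 1044L,
                Greenhouse = 62L)
  tot <- tapply(x$planted, x$location, sum)[names(expected)]
  if (any(x$germinated > x$planted) ||
      !identical(as.integer(tot), as.integer(expected)) ||
      sum(x$planted) != 10588L) {
    stop("packaged seed-count table failed its integrity check", call. = FALSE)
  }
  x
}

#' Build the fixed-effect design for the germination regressions
#'
#' Encodes the four treatment factors as treatment-contrast dummies
#' (reference levels omitted, deterministic column order following
#' [trial_levels()]) and provenance as an integer grouping index. The age
#' covariate is not part of this matrix: seed age enters the models as a
#' per-depth-slice quantity, standardized and (optionally) latent, so the
#' design object records each row's depth slice instead.
#'
#' @param trials Validated trial table (see [validate_trials()]).
#' @param reference_levels Named character vector as in
#'   [default_reference_levels()]; must name all four factors with levels
#'   present in the declared sets.
#' @return An object of class `germ_design`: list with elements `X`
#'   (numeric matrix of treatment dummies), `column_names`,
#'   `reference_levels`, `provenance_index`, `provenance_levels`,
#'   `depth_interval`, `depth_cm`, `n_planted`, `y`.
#' @export
build_design <- function(trials, reference_levels = default_reference_levels()) {
  lv <- trial_levels()
  if (!all(names(lv) %in% names(reference_levels))) {
    stop("reference_levels must name all of: ",
         paste(names(lv), collapse = ", "), call. = FALSE)
  }
  for (f in names(lv)) {
    if (!reference_levels[[f]] %in% lv[[f]]) {
      stop("reference level '", reference_levels[[f]],
           "' is not a declared level of ", f, call. = FALSE)
    }
  }
  trials <- validate_trials(trials)

  blocks <- lapply(names(lv), function(f) {
    ref <- reference_levels[[f]]
    others <- setdiff(lv[[f]], ref)
    m <- sapply(others, function(l) as.numeric(trials[[f]] == l))
    m <- matrix(m, nrow = nrow(trials),
                dimnames = list(NULL, paste0(f, ":", others)))
    m
  })
  X <- do.call(cbind, blocks)

  prov_levels <- sort(unique(trials$provenance))
  structure(list(
    X = X,
    column_names = colnames(X),
    reference_levels = reference_levels,
    provenance_index = match(trials$provenance, prov_levels),
    provenance_levels = prov_levels,
    depth_interval = trials$depth_interval_id,
    depth_cm = trials$depth_cm,
    n_planted = trials$n_planted,
    y = trials$n_germinated
  ), class = "germ_design")
}

#' @export
print.germ_design <- function(x, ...) {
  cat("<germ_design> ", nrow(x$X), " trial groups, ",
      ncol(x$X), " treatment dummies, ",
      length(x$provenance_levels), " provenances, ",
      length(unique(x$depth_interval)), " depth slices\n", sep = "")
  invisible(x)
}
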