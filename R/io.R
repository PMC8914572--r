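## Analysis-facing columns per file; latent quantities go to oracle files only.
.SURGEON_COLS <- c("surgeon_id", "annual_volume", "age", "male",
                   "multi_hospital", "primary_hospital_id", "hospital_ids",
                   "location_id")
.HOSPITAL_COLS <- c("hospital_id", "annual_volume", "cardiac_icu", "ownership",
                    "teaching", "size", "location_id")

#' Write a synthetic claims bundle as delimited text files
#'
#' Emits `patients.csv`, `surgeons.csv`, `hospitals.csv` and a long-format
#' `travel.csv` (location pairs and driving hours between patient and provider
#' locations), all analysis-facing.  Latent quantities (provider quality,
#' patient frailty, true linear predictors) are written separately to
#' `oracle_patients.csv` / `oracle_providers.csv`, clearly namespaced as
#' oracle-only; the analysis path never reads them and runs fine if they are
#' deleted.
#'
#' @param claims a `volemu_claims` bundle from [simulate_claims()] (or a list
#'   with the same elements).
#' @param path directory to write into (created if needed).
#' @param oracle write the oracle-only files too?
#' @return Invisibly, the character vector of files written.
#' @export
write_claims <- function(claims, path, oracle = TRUE) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) {
    f <- file.path(path, file)
    tryCatch(write.csv(df, f, row.names = FALSE, quote = FALSE),
             error = function(e) stop(sprintf("failed writing %s: %s", f,
                                              conditionMessage(e)),
                                      call. = FALSE))
    f
  }
  loc <- claims$travel$locations
  pat_loc <- loc$location_id[!loc$outlying_provider %||% FALSE]
  prov_loc <- unique(c(claims$surgeons$location_id,
                       claims$hospitals$location_id))
  H <- travel_matrix(claims$travel, pat_loc, prov_loc)
  travel_long <- data.frame(
    patient_location = rep(rownames(H), times = ncol(H)),
    provider_location = rep(colnames(H), each = nrow(H)),
    hours = as.vector(H)
  )
  files <- c(
    wr(claims$patients, "patients.csv"),
    wr(claims$surgeons[, .SURGEON_COLS], "surgeons.csv"),
    wr(claims$hospitals[, .HOSPITAL_COLS], "hospitals.csv"),
    wr(cbind(loc[c("location_id", "x", "y")],
             hours_per_unit = claims$travel$hours_per_unit,
             remote = as.integer(loc$remote %||% FALSE),
             outlying_provider = as.integer(loc$outlying_provider %||% FALSE)),
       "locations.csv"),
    wr(travel_long, "travel.csv")
  )
  if (oracle) {
    orc <- attr(claims$patients, "oracle")
    if (!is.null(orc)) files <- c(files, wr(orc, "oracle_patients.csv"))
    files <- c(files, wr(
      rbind(
        data.frame(provider_id = claims$surgeons$surgeon_id,
                   latent_quality = claims$surgeons$latent_quality),
        data.frame(provider_id = claims$hospitals$hospital_id,
                   latent_quality = claims$hospitals$latent_quality)
      ), "oracle_providers.csv"))
  }
  invisible(files)
}

#' @keywords internal
.read_checked <- function(file, required) {
  if (!file.exists(file)) stop("missing claims file: ", file, call. = FALSE)
  df <- tryCatch(read.csv(file, stringsAsFactors = FALSE),
                 error = function(e) stop(sprintf("failed parsing %s: %s",
                                                  file, conditionMessage(e)),
                                          call. = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: malformed header, missing column(s) %s", basename(file),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyNA(df[required])) {
    stop(sprintf("%s: missing values in analysis-facing column(s)",
                 basename(file)), call. = FALSE)
  }
  df
}

#' Read a claims bundle written by [write_claims()]
#'
#' The round trip is lossless for all analysis-facing fields.  Oracle files
#' are re-attached when present but their absence is not an error.
#'
#' @param path directory containing the claims CSVs.
#' @return A `volemu_claims` bundle.
#' @export
read_claims <- function(path) {
  patients <- .read_checked(file.path(path, "patients.csv"),
                            c("patient_id", "age", "operation_date",
                              "location_id", "surgeon_id", "hospital_id",
                              "death_90d"))
  patients$operation_date <- as.Date(patients$operation_date)
  surgeons <- .read_checked(file.path(path, "surgeons.csv"), .SURGEON_COLS)
  hospitals <- .read_checked(file.path(path, "hospitals.csv"), .HOSPITAL_COLS)
  locs <- .read_checked(file.path(path, "locations.csv"),
                        c("location_id", "x", "y", "hours_per_unit"))
  travel <- make_travel(
    data.frame(location_id = locs$location_id, x = locs$x, y = locs$y,
               remote = as.logical(locs$remote %||% FALSE),
               outlying_provider = as.logical(locs$outlying_provider %||% FALSE),
               stringsAsFactors = FALSE),
    locs$hours_per_unit[1]
  )
  op <- file.path(path, "oracle_patients.csv")
  if (file.exists(op)) {
    orc <- read.csv(op, stringsAsFactors = FALSE)
    attr(patients, "oracle") <- orc
  }
  opr <- file.path(path, "oracle_providers.csv")
  if (file.exists(opr)) {
    q <- read.csv(opr, stringsAsFactors = FALSE)
    surgeons$latent_quality <-
      q$latent_quality[match(surgeons$surgeon_id, q$provider_id)]
    hospitals$latent_quality <-
      q$latent_quality[match(hospitals$hospital_id, q$provider_id)]
  }
  structure(list(patients = patients, surgeons = surgeons,
                 hospitals = hospitals, travel = travel, params = NULL),
            class = "volemu_claims")
}
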