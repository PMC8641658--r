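# Domain containers, delimited-text IO and the study eligibility filter.

#' Recognised laboratory analytes
#'
#' The five analytes the allograft-function scores consume, with their
#' canonical units: AST and ALT in IU/L, total bilirubin (TBIL) in mg/dL,
#' INR dimensionless and platelets (PLT) in 10^9/L.
#'
#' @export
LAB_ANALYTES <- c("AST", "ALT", "TBIL", "INR", "PLT")

# umol/L -> mg/dL for bilirubin
TBIL_UMOL_PER_MGDL <- 17.104

# Exclusion categories in the order they are tallied; a patient is counted
# once, under the first matching category.
EXCLUSION_CATEGORIES <- c(
  "age_lt18", "acute_liver_failure", "retransplantation", "multivisceral",
  "split", "living_donor", "early_vascular_complication", "insufficient_labs"
)

#' Construct a post-transplant cohort
#'
#' A cohort bundles three aligned tables keyed by `patient_id`: a long-format
#' laboratory table (`labs`: patient_id, pod, analyte, value in canonical
#' units), a one-row-per-patient clinical table (`clinical`) and an outcome
#' table (`outcomes`: follow_up_days, death/retransplant flags and days).
#'
#' @param labs data.frame with columns patient_id, pod, analyte, value.
#' @param clinical data.frame with one row per patient (column patient_id).
#' @param outcomes data.frame with columns patient_id, follow_up_days,
#'   death, death_day, retransplant, retransplant_day.
#' @return An object of class `graft_cohort`.
#' @export
new_cohort <- function(labs, clinical, outcomes) {
  validate_labs(labs)
  stopifnot(is.data.frame(clinical), "patient_id" %in% names(clinical))
  stopifnot(is.data.frame(outcomes),
            all(c("patient_id", "follow_up_days", "death", "death_day",
                  "retransplant", "retransplant_day") %in% names(outcomes)))
  ids <- as.character(clinical$patient_id)
  if (anyDuplicated(ids)) stop("duplicate patient_id in clinical table")
  if (!setequal(ids, as.character(outcomes$patient_id)))
    stop("clinical and outcome tables must cover the same patients")
  extra <- setdiff(unique(as.character(labs$patient_id)), ids)
  if (length(extra))
    stop("labs reference unknown patients: ", paste(extra, collapse = ", "))
  bad <- with(outcomes,
              (death & death_day > follow_up_days) |
              (retransplant & retransplant_day > follow_up_days))
  if (any(bad, na.rm = TRUE))
    stop("event day after follow-up for: ",
         paste(outcomes$patient_id[which(bad)], collapse = ", "))
  structure(list(labs = labs, clinical = clinical, outcomes = outcomes),
            class = "graft_cohort")
}

validate_labs <- function(labs) {
  stopifnot(is.data.frame(labs),
            all(c("patient_id", "pod", "analyte", "value") %in% names(labs)))
  if (!nrow(labs)) return(invisible(labs))
  unknown <- !labs$analyte %in% LAB_ANALYTES
  if (any(unknown))
    stop("unknown analyte(s): ",
         paste(unique(labs$analyte[unknown]), collapse = ", "))
  if (any(labs$pod != round(labs$pod)) || any(labs$pod < 0))
    stop("PODs must be non-negative integers")
  npos <- !is.finite(labs$value) | labs$value <= 0
  if (any(npos)) {
    i <- which(npos)[1L]
    stop(sprintf(
      "non-positive %s value for patient %s at POD %d (log-transform undefined)",
      labs$analyte[i], labs$patient_id[i], as.integer(labs$pod[i])))
  }
  key <- paste(labs$patient_id, labs$analyte, labs$pod)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("duplicate observation: patient %s, %s, POD %d",
                 labs$patient_id[i], labs$analyte[i], as.integer(labs$pod[i])))
  }
  invisible(labs)
}

#' @export
print.graft_cohort <- function(x, ...) {
  cat(sprintf("<graft_cohort> %d patients, %d lab observations\n",
              nrow(x$clinical), nrow(x$labs)))
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort a `graft_cohort`.
#' @export
n_patients <- function(cohort) nrow(cohort$clinical)

#' Laboratory series for one patient
#'
#' @param cohort a `graft_cohort`.
#' @param patient_id patient identifier.
#' @return data.frame with columns pod, analyte, value (canonical units).
#' @export
lab_series <- function(cohort, patient_id) {
  labs <- cohort$labs
  labs[labs$patient_id == patient_id, c("pod", "analyte", "value"),
       drop = FALSE]
}

# Outcome columns carried inside the clinical CSV so read/write stay two-file.
OUTCOME_COLS <- c("follow_up_days", "death", "death_day",
                  "retransplant", "retransplant_day")

#' Read a cohort from delimited text
#'
#' The labs file is long-format CSV with columns `patient_id, pod, analyte,
#' value, unit`; the clinical file has one row per patient and carries the
#' covariates, exclusion flags (`excl_*`, encoded 0/1) and outcome fields.
#' Values are converted to canonical units on ingest: TBIL reported in
#' umol/L is divided by 17.104 to mg/dL. Unparseable rows are reported with
#' their line numbers.
#'
#' @param lab_path path to the labs CSV.
#' @param clinical_path path to the clinical CSV.
#' @return A `graft_cohort`.
#' @export
read_cohort <- function(lab_path, clinical_path) {
  labs <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "pod", "analyte", "value")
  if (!all(need %in% names(labs)))
    stop("labs file must have columns: ", paste(need, collapse = ", "))
  if (!"unit" %in% names(labs)) labs$unit <- ""
  labs$patient_id <- as.character(labs$patient_id)

  bad <- which(!labs$analyte %in% LAB_ANALYTES | !is.finite(labs$value))
  if (length(bad))
    stop("unparseable labs rows (file line numbers): ",
         paste(bad + 1L, collapse = ", "))

  umol <- labs$analyte == "TBIL" &
    tolower(labs$unit) %in% c("umol/l", "µmol/l", "micromol/l")
  labs$value[umol] <- labs$value[umol] / TBIL_UMOL_PER_MGDL
  labs$unit <- NULL

  clin <- utils::read.csv(clinical_path, stringsAsFactors = FALSE)
  clin$patient_id <- as.character(clin$patient_id)
  missing_out <- setdiff(OUTCOME_COLS, names(clin))
  if (length(missing_out))
    stop("clinical file lacks outcome columns: ",
         paste(missing_out, collapse = ", "))
  for (cl in grep("^excl_|^death$|^retransplant$|_ge70$|^thrombosis",
                  names(clin), value = TRUE))
    clin[[cl]] <- as.logical(clin[[cl]])
  for (cl in c("follow_up_days", "death_day", "retransplant_day"))
    clin[[cl]] <- as.numeric(clin[[cl]])
  outcomes <- clin[, c("patient_id", OUTCOME_COLS)]
  clinical <- clin[, setdiff(names(clin), OUTCOME_COLS), drop = FALSE]
  new_cohort(labs, clinical, outcomes)
}

#' Write a cohort to delimited text
#'
#' Inverse of [read_cohort()]: values are written in canonical units with a
#' unit column, numerics at full double precision so a read/write round trip
#' is lossless.
#'
#' @param cohort a `graft_cohort`.
#' @param lab_path,clinical_path output CSV paths.
#' @export
write_cohort <- function(cohort, lab_path, clinical_path) {
  labs <- cohort$labs
  labs$unit <- c(AST = "IU/L", ALT = "IU/L", TBIL = "mg/dL",
                 INR = "", PLT = "10^9/L")[labs$analyte]
  fmt <- function(df) {
    for (cl in names(df)) {
      if (is.double(df[[cl]]))
        df[[cl]] <- vapply(df[[cl]], function(v)
          if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE,
                                       trim = TRUE), "")
      if (is.logical(df[[cl]])) df[[cl]] <- as.integer(df[[cl]])
    }
    df
  }
  utils::write.csv(fmt(labs), lab_path, row.names = FALSE, quote = FALSE)
  clin <- merge(cohort$clinical, cohort$outcomes, by = "patient_id",
                sort = FALSE)
  utils::write.csv(fmt(clin), clinical_path, row.names = FALSE, quote = FALSE)
  invisible(cohort)
}

#' Apply the study eligibility filter
#'
#' Removes patients flagged for any exclusion criterion (recipient age under
#' 18, transplant for acute liver failure, retransplantation, multivisceral
#' or split or living-donor transplant, early vascular complication within
#' 14 days) or whose laboratory coverage is insufficient to compute the
#' requested scores. Each excluded patient is tallied once, under the first
#' matching category in the printed order.
#'
#' @param cohort a `graft_cohort` whose clinical table carries `excl_*` flag
#'   columns (absent columns are treated as all-FALSE).
#' @param require_models score models whose lab coverage defines
#'   "insufficient labs"; defaults to the 7-day models that every retained
#'   patient must support.
#' @return list with elements `cohort` (filtered) and `tally` (named integer
#'   vector over all exclusion categories).
#' @export
apply_exclusions <- function(cohort,
                             require_models = c("ead", "meaf", "lgraft7")) {
  clin <- cohort$clinical
  n <- nrow(clin)
  flag <- function(col) {
    if (col %in% names(clin)) isTRUE_vec(clin[[col]]) else rep(FALSE, n)
  }
  flags <- cbind(
    age_lt18                    = flag("excl_age_lt18"),
    acute_liver_failure         = flag("excl_acute_liver_failure"),
    retransplantation           = flag("excl_retransplantation"),
    multivisceral               = flag("excl_multivisceral"),
    split                       = flag("excl_split"),
    living_donor                = flag("excl_living_donor"),
    early_vascular_complication = flag("excl_early_vascular"),
    insufficient_labs           = !vapply(clin$patient_id, function(id) {
      labs <- lab_series(cohort, id)
      all(vapply(require_models, function(m)
        isTRUE(extract_features(labs, m)$sufficient), logical(1)))
    }, logical(1))
  )
  first <- apply(flags, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1L] else 0L
  })
  tally <- vapply(seq_along(EXCLUSION_CATEGORIES),
                  function(k) sum(first == k), integer(1))
  names(tally) <- EXCLUSION_CATEGORIES
  keep <- clin$patient_id[first == 0L]
  list(cohort = subset_cohort(cohort, keep), tally = tally)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Restrict a cohort to a set of patients
#' @param cohort a `graft_cohort`.
#' @param patient_ids identifiers to keep.
#' @export
subset_cohort <- function(cohort, patient_ids) {
  new_cohort(
    cohort$labs[cohort$labs$patient_id %in% patient_ids, , drop = FALSE],
    cohort$clinical[cohort$clinical$patient_id %in% patient_ids, , drop = FALSE],
    cohort$outcomes[cohort$outcomes$patient_id %in% patient_ids, , drop = FALSE]
  )
}
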