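# Fixture builders: everything is constructed in code at test time.

# long-format labs for one patient; scalar values are recycled across pods
make_labs <- function(values, pods = 1:7) {
  if (!length(pods))
    return(data.frame(pod = integer(0), analyte = character(0),
                      value = numeric(0)))
  do.call(rbind, lapply(names(values), function(a) {
    v <- values[[a]]
    if (length(v) == 1L) v <- rep(v, length(pods))
    data.frame(pod = pods, analyte = a, value = v)
  }))
}

# physiologically unremarkable labs over the given pods
normal_labs <- function(pods = 1:10) {
  make_labs(list(AST = 150, ALT = 120, TBIL = 2, INR = 1.1, PLT = 120),
            pods = pods)
}

# minimal clinical row with the EASE covariates and no exclusion flags
make_clinical <- function(patient_id = "P1", meld = 15, rbc_units = 4,
                          thrombosis = FALSE, center_ge70 = TRUE, ...) {
  data.frame(patient_id = patient_id, meld = meld, rbc_units = rbc_units,
             thrombosis_days_1_10 = thrombosis,
             center_volume_ge70 = center_ge70, ...)
}

make_outcomes <- function(patient_id = "P1", follow_up_days = 400,
                          death = FALSE, death_day = NA_real_,
                          retransplant = FALSE,
                          retransplant_day = NA_real_) {
  data.frame(patient_id = patient_id, follow_up_days = follow_up_days,
             death = death, death_day = death_day,
             retransplant = retransplant,
             retransplant_day = retransplant_day)
}

# assemble a cohort from per-patient labs (named list id -> labs df)
make_cohort <- function(labs_by_id, clinical = NULL, outcomes = NULL) {
  ids <- names(labs_by_id)
  labs <- do.call(rbind, lapply(ids, function(id)
    cbind(patient_id = id, labs_by_id[[id]])))
  if (is.null(clinical))
    clinical <- do.call(rbind, lapply(ids, function(id)
      make_clinical(patient_id = id)))
  if (is.null(outcomes))
    outcomes <- do.call(rbind, lapply(ids, function(id)
      make_outcomes(patient_id = id)))
  new_cohort(labs, clinical, outcomes)
}

# brute-force pairwise AUROC: mean of event-beats-survivor indicators
brute_auroc <- function(scores, labels) {
  ev <- scores[as.logical(labels)]
  sv <- scores[!as.logical(labels)]
  mean(outer(ev, sv, function(x, y) (x > y) + 0.5 * (x == y)))
}
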