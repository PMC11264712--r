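# Economic primitives: QALY/cost derivation per patient, pairwise INMB,
# the adoption rule, and pairing of patient records by arrival order.

# EQ-5D (UK value set) utility range
.u_range <- c(-0.594, 1)

#' Derive total cost and QALYs for one patient record
#'
#' Total follow-up cost is the sum of the record's cost components. QALYs
#' are the area under the utility curve over the follow-up window,
#' computed by the trapezoidal rule from EQ-5D-style utilities measured at
#' baseline, 6 and 12 months (baseline and 6 months only when the window
#' is six months).
#'
#' @param record A single patient record: a list or one-row data frame
#'   with utilities `u0`, `u6` (and `u12` for a 12-month window) and cost
#'   components in fields whose names start with `cost_`.
#' @param delta_years Length of the follow-up window in years (1 or 0.5).
#' @return A list with components `total_cost` (GBP) and `qaly`.
#' @examples
#' derive_costs_and_qalys(list(u0 = 0.8, u6 = 0.6, u12 = 0.4,
#'                             cost_1 = 100, cost_2 = 50))
#' @export
derive_costs_and_qalys <- function(record, delta_years = 1) {
  record <- as.list(record)
  uf <- if (delta_years >= 0.75) c("u0", "u6", "u12") else c("u0", "u6")
  for (f in uf) {
    v <- record[[f]]
    if (is.null(v) || is.na(v))
      stop("missing utility field '", f, "'", call. = FALSE)
    if (v < .u_range[1] || v > .u_range[2])
      stop("utility '", f, "' = ", v, " outside [", .u_range[1], ", ",
           .u_range[2], "]", call. = FALSE)
  }
  cf <- grep("^cost_", names(record), value = TRUE)
  costs <- unlist(record[cf], use.names = TRUE)
  if (any(is.na(costs))) {
    bad <- names(costs)[is.na(costs)][1]
    stop("missing cost field '", bad, "'", call. = FALSE)
  }
  u <- unlist(record[uf])
  # trapezoid over equally spaced assessments spanning delta_years
  k <- length(u) - 1L
  qaly <- sum((u[-1] + u[-length(u)]) / 2) * (delta_years / k)
  list(total_cost = sum(costs), qaly = unname(qaly))
}

#' Pairwise incremental net monetary benefit
#'
#' For a pair of records randomised to the new technology (arm `"N"`) and
#' the standard (arm `"S"`), the incremental net monetary benefit is
#' `lambda * (E_N - E_S) - (C_N - C_S)`, where E denotes QALYs and C total
#' cost over the follow-up window. Positive values favour the new
#' technology.
#'
#' @param record_n,record_s Patient records (see
#'   [derive_costs_and_qalys()]) with an `arm` field equal to `"N"` and
#'   `"S"` respectively.
#' @param lambda_wtp Willingness to pay per QALY (GBP).
#' @param delta_years Follow-up window in years.
#' @return Pairwise INMB in GBP.
#' @export
compute_inmb <- function(record_n, record_s, lambda_wtp = 30000,
                         delta_years = 1) {
  record_n <- as.list(record_n); record_s <- as.list(record_s)
  an <- record_n$arm; as_ <- record_s$arm
  if (!is.null(an) && !is.null(as_) && (an != "N" || as_ != "S"))
    stop("mismatched arms: expected one 'N' and one 'S' record", call. = FALSE)
  en <- derive_costs_and_qalys(record_n, delta_years)
  es <- derive_costs_and_qalys(record_s, delta_years)
  lambda_wtp * (en$qaly - es$qaly) - (en$total_cost - es$total_cost)
}

#' Technology adoption decision
#'
#' The new technology is recommended when the total expected reward to the
#' adoption population strictly exceeds the switching cost, i.e. when
#' `P * mu_final > I`. Ties keep the standard technology.
#'
#' @param mu_final Final posterior mean of E\[INMB\] (GBP).
#' @param P Patients affected by the adoption decision.
#' @param I Switching cost (GBP).
#' @return `"adopt_N"` or `"keep_S"`.
#' @examples
#' adoption_decision(-30, P = 24500)   # "keep_S"
#' @export
adoption_decision <- function(mu_final, P, I = 0) {
  if (P * mu_final > I) "adopt_N" else "keep_S"
}

#' Pair patient records by order of arrival
#'
#' Patients are paired across arms by the rank of their randomisation date
#' within arm: the i-th patient randomised to the new technology is paired
#' with the i-th randomised to the standard. Surplus unpaired patients in
#' the larger arm are dropped with a warning.
#'
#' @param records Data frame of patient records with columns `id`, `arm`
#'   (`"N"`/`"S"`) and `rand_date` (days since trial start).
#' @return A data frame with one row per pair: `pair_index`,
#'   `id_N`, `id_S`, `rand_date` (the later of the two dates), and the
#'   original row indices `row_N`, `row_S`.
#' @export
pair_patients <- function(records) {
  stopifnot(is.data.frame(records), all(c("arm", "rand_date") %in% names(records)))
  iN <- which(records$arm == "N"); iS <- which(records$arm == "S")
  iN <- iN[order(records$rand_date[iN])]
  iS <- iS[order(records$rand_date[iS])]
  k <- min(length(iN), length(iS))
  if (length(iN) != length(iS))
    warning(abs(length(iN) - length(iS)),
            " unpaired surplus patient(s) dropped from arm ",
            if (length(iN) > length(iS)) "N" else "S", call. = FALSE)
  iN <- iN[seq_len(k)]; iS <- iS[seq_len(k)]
  data.frame(pair_index = seq_len(k),
             id_N = if ("id" %in% names(records)) records$id[iN] else iN,
             id_S = if ("id" %in% names(records)) records$id[iS] else iS,
             rand_date = pmax(records$rand_date[iN], records$rand_date[iS]),
             row_N = iN, row_S = iS)
}

#' Pairwise INMB observations for a paired cohort
#'
#' Applies [compute_inmb()] to every pair returned by [pair_patients()],
#' in arrival order.
#'
#' @param records Complete (no missing fields) patient record data frame.
#' @param lambda_wtp Willingness to pay per QALY (GBP).
#' @param delta_years Follow-up window in years.
#' @return Numeric vector of pairwise INMB values, one per pair, ordered
#'   by pair index.
#' @export
cohort_inmb <- function(records, lambda_wtp = 30000, delta_years = 1) {
  pr <- pair_patients(records)
  vapply(seq_len(nrow(pr)), function(i) {
    compute_inmb(records[pr$row_N[i], , drop = FALSE],
                 records[pr$row_S[i], , drop = FALSE],
                 lambda_wtp, delta_years)
  }, numeric(1))
}

#' Read and write patient record files
#'
#' Patient records are exchanged as plain CSV with header columns `id`,
#' `arm` (`"N"` or `"S"`), `rand_date` (days since trial start), utilities
#' `u0`, `u6`, `u12`, one or more cost components `cost_1`, `cost_2`, ...,
#' and optional baseline covariates `cov_*`. Missing values are empty
#' cells or `NA`.
#'
#' @param path File path.
#' @param records Data frame of patient records.
#' @return `read_patient_csv()` returns a data frame;
#'   `write_patient_csv()` returns `path` invisibly.
#' @export
read_patient_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "arm", "rand_date", "u0", "u6")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("patient file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_patient_csv
#' @export
write_patient_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
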