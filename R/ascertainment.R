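#' Apply the composite case definition to merged infant records
#'
#' Flags each infant for the seven conditions of the composite brain-injury
#' definition by intersecting the infant's code set with each condition's
#' catalog tokens, applying population restrictions (cPVL counts for infants
#' born before 37 completed weeks only). The composite status counts each
#' infant once regardless of how many conditions are present:
#' `composite_before` is the OR of the seven flags; `composite_after`
#' additionally applies the congenital-exclusion rule (see
#' [apply_exclusion_rule()]).
#'
#' Tokens not present in the catalog are ignored: unknown codes must not
#' crash surveillance. If any are seen a single warning lists them (disable
#' with `warn_unknown = FALSE`); the full set is kept in the
#' `unknown_tokens` attribute.
#'
#' @param infants Infant-record tibble from [merge_to_infants()] (needs
#'   `infant_id`, `gestational_weeks`, `codes`; `year` is carried through if
#'   present).
#' @param catalog A [condition_catalog()].
#' @param warn_unknown Warn when codes absent from the catalog are seen?
#' @return A tibble with one row per infant: the seven condition flags,
#'   `severe_pivh` (intracranial haemorrhage via a severe-subset token),
#'   `has_exclusion_code`, `composite_before`, `composite_after`, `excluded`
#'   and `exclusion_reason`.
#' @export
classify_infants <- function(infants, catalog = condition_catalog(),
                             warn_unknown = TRUE) {
  catalog <- validate_catalog(catalog)
  infants <- as_tibble(infants)
  n <- nrow(infants)
  code_list <- split_codes(infants$codes)
  tokens <- unlist(code_list, use.names = FALSE)
  row_of <- rep(seq_len(n), lengths(code_list))

  flag_for <- function(token_set) {
    out <- logical(n)
    out[unique(row_of[tokens %in% token_set])] <- TRUE
    out
  }

  res <- tibble(infant_id = infants$infant_id)
  if ("year" %in% names(infants)) res$year <- infants$year
  res$gestational_weeks <- infants$gestational_weeks

  preterm <- !is.na(infants$gestational_weeks) & infants$gestational_weeks < 37
  for (nm in names(catalog$conditions)) {
    cond <- catalog$conditions[[nm]]
    flag <- flag_for(cond$tokens)
    if (identical(cond$restriction, "preterm")) flag <- flag & preterm
    res[[nm]] <- flag
  }
  severe <- catalog$conditions$intracranial_haemorrhage$severe_tokens
  res$severe_pivh <- if (is.null(severe)) {
    rep(FALSE, n)
  } else {
    flag_for(severe) & res$intracranial_haemorrhage
  }
  res$has_exclusion_code <- flag_for(catalog$exclusions)

  unknown <- setdiff(unique(tokens), catalog_tokens(catalog))
  if (length(unknown) && warn_unknown) {
    warn(sprintf("ignoring %d code(s) not in the catalog: %s",
                 length(unknown),
                 paste(head(unknown, 5), collapse = ", ")))
  }

  cond_names <- intersect(names(catalog$conditions), names(res))
  res$composite_before <- Reduce(`|`, res[cond_names])
  res <- apply_exclusion_rule(res, condition_names = cond_names)
  attr(res, "unknown_tokens") <- unknown
  res
}

#' Exclude seizure-only cases with congenital conditions
#'
#' The composite definition is reported before and after excluding infants
#' with seizures who also carry a diagnosis indicating that the brain injury
#' occurred before birth (congenital encephalopathy, congenital infection or
#' congenital brain abnormality). The exclusion is deliberately narrow: an
#' infant qualifying through any non-seizure condition is never excluded,
#' however many congenital codes are present.
#'
#' @param results Classification tibble with the condition flags,
#'   `composite_before` and `has_exclusion_code` (as from
#'   [classify_infants()], which already applies this rule; exported so the
#'   rule can be re-applied after editing flags).
#' @param condition_names Names of the condition flag columns.
#' @return `results` with recomputed `composite_after`, `excluded` and
#'   `exclusion_reason`.
#' @export
apply_exclusion_rule <- function(results,
                                 condition_names = condition_flags()) {
  condition_names <- intersect(condition_names, names(results))
  other <- setdiff(condition_names, "seizures")
  non_seizure_basis <- if (length(other)) {
    Reduce(`|`, results[other])
  } else {
    rep(FALSE, nrow(results))
  }
  seizure_only <- results$seizures & !non_seizure_basis
  results$composite_after <- results$composite_before &
    !(seizure_only & results$has_exclusion_code)
  results$excluded <- results$composite_before & !results$composite_after
  results$exclusion_reason <- ifelse(
    results$excluded, "congenital_condition_seizures_only", NA_character_)
  results
}

#' Names of the condition flag columns
#'
#' @return Character vector of the seven condition names used as flag
#'   columns throughout the package.
#' @export
condition_flags <- function() condition_names()

#' Count cases by gestational-age stratum
#'
#' Tallies composite cases (each infant counted once, before and after
#' exclusions) and per-condition cases (an infant counted once per condition
#' held) for the strata used in national reporting: all infants, term
#' (>= 37 weeks), preterm (< 37 weeks) and the < 32 and < 34 week subgroups.
#' Infants with missing gestational age are counted in `all` only and
#' reported under the `missing_ga` measure.
#'
#' @param results Classification tibble from [classify_infants()].
#' @return A tibble with columns `year` (if present in `results`), `stratum`,
#'   `measure`, `count`.
#' @export
count_cases <- function(results) {
  ga <- results$gestational_weeks
  strata <- list(
    all = rep(TRUE, nrow(results)),
    term = !is.na(ga) & ga >= 37,
    preterm = !is.na(ga) & ga < 37,
    lt32 = !is.na(ga) & ga < 32,
    lt34 = !is.na(ga) & ga < 34
  )
  cond_names <- intersect(condition_names(), names(results))
  years <- if ("year" %in% names(results)) results$year else NA_integer_

  one_block <- function(sub) {
    measures <- c("admitted_infants", "composite_before", "composite_after",
                  "n_excluded", cond_names,
                  if ("severe_pivh" %in% names(sub)) "severe_pivh",
                  "missing_ga")
    counts <- c(
      nrow(sub), sum(sub$composite_before), sum(sub$composite_after),
      sum(sub$excluded),
      vapply(cond_names, function(nm) sum(sub[[nm]]), numeric(1)),
      if ("severe_pivh" %in% names(sub)) sum(sub$severe_pivh),
      sum(is.na(sub$gestational_weeks))
    )
    tibble(measure = measures, count = as.integer(counts))
  }

  blocks <- lapply(unique(years), function(y) {
    in_year <- if (is.na(y)) rep(TRUE, nrow(results)) else years == y
    purrr::imap(strata, function(keep, nm) {
      one_block(results[in_year & keep, , drop = FALSE]) |>
        mutate(stratum = nm, year = y, .before = 1)
    }) |> bind_rows()
  })
  out <- bind_rows(blocks) |> select("year", "stratum", "measure", "count")
  if (all(is.na(out$year))) out$year <- NULL
  out
}
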