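#' Condition catalog for the composite brain-injury case definition
#'
#' Builds the catalog mapping raw diagnosis/observation tokens found in
#' episode records to the seven conditions of the composite case definition
#' (seizures; intracranial haemorrhage; perinatal/neonatal stroke;
#' hypoxic-ischaemic encephalopathy, HIE; central nervous system infection;
#' bilirubin encephalopathy/kernicterus; cystic periventricular leucomalacia,
#' cPVL), plus the exclusion set of congenital conditions indicating that
#' brain injury occurred before birth (congenital encephalopathies including
#' inborn errors of metabolism, congenital infections, congenital brain
#' abnormalities).
#'
#' The shipped tokens are a configurable stand-in vocabulary, not the
#' registry's proprietary field codes; real deployments supply their own
#' catalog via [read_catalog()]. cPVL carries the population restriction
#' `"preterm"`: it only counts for infants born before 37 completed weeks.
#' Intracranial haemorrhage carries a `severe_tokens` subset (grade 3-4
#' intraventricular/periventricular haemorrhage) used for the severe P/IVH
#' tally. HIE tokens carry a severity attribute; `include_mild_hie = FALSE`
#' restricts the condition to moderate/severe HIE.
#'
#' @param include_mild_hie Keep mild HIE in the HIE token set? The composite
#'   definition names HIE unqualified, but surveillance consumers sometimes
#'   restrict to moderate/severe; this is a configuration choice, not a fixed
#'   answer.
#' @return An object of class `condition_catalog`: a list with elements
#'   `conditions` (named list of `tokens`, `restriction`, optional
#'   `severe_tokens`) and `exclusions` (character vector of tokens).
#' @export
#' @examples
#' cat7 <- condition_catalog()
#' names(cat7$conditions)
condition_catalog <- function(include_mild_hie = TRUE) {
  hie_tokens <- c(hie_mild = "mild", hie_moderate = "moderate",
                  hie_severe = "severe")
  if (!include_mild_hie) hie_tokens <- hie_tokens[-1]
  catalog <- list(
    conditions = list(
      seizures = list(
        tokens = c("seizure_clinical", "seizure_eeg_confirmed",
                   "seizure_unspecified"),
        restriction = "all"
      ),
      intracranial_haemorrhage = list(
        tokens = c("ivh_grade1", "ivh_grade2", "ivh_grade3", "ivh_grade4",
                   "subdural_haemorrhage", "subarachnoid_haemorrhage",
                   "parenchymal_haemorrhage"),
        restriction = "all",
        severe_tokens = c("ivh_grade3", "ivh_grade4")
      ),
      stroke = list(
        tokens = c("arterial_ischaemic_stroke",
                   "cerebral_sinovenous_thrombosis"),
        restriction = "all"
      ),
      hie = list(
        tokens = names(hie_tokens),
        restriction = "all",
        severity = hie_tokens
      ),
      cns_infection = list(
        tokens = c("bacterial_meningitis", "viral_meningitis",
                   "encephalitis", "ventriculitis"),
        restriction = "all"
      ),
      bilirubin_encephalopathy = list(
        tokens = c("kernicterus", "acute_bilirubin_encephalopathy"),
        restriction = "all"
      ),
      cpvl = list(
        tokens = c("cystic_pvl"),
        restriction = "preterm"
      )
    ),
    exclusions = c("congenital_encephalopathy", "inborn_error_metabolism",
                   "congenital_infection", "congenital_brain_abnormality")
  )
  validate_catalog(catalog)
}

validate_catalog <- function(catalog) {
  if (!is.list(catalog) || !all(c("conditions", "exclusions") %in% names(catalog))) {
    abort("a condition catalog needs `conditions` and `exclusions`",
          class = "neosurv_catalog_error")
  }
  inclusion <- unlist(lapply(catalog$conditions, `[[`, "tokens"), use.names = FALSE)
  if (anyDuplicated(inclusion)) {
    abort("condition token sets must not share tokens",
          class = "neosurv_catalog_error")
  }
  overlap <- intersect(inclusion, catalog$exclusions)
  if (length(overlap)) {
    abort(sprintf("tokens in both inclusion and exclusion sets: %s",
                  paste(overlap, collapse = ", ")),
          class = "neosurv_catalog_error")
  }
  for (nm in names(catalog$conditions)) {
    cond <- catalog$conditions[[nm]]
    cond$restriction <- cond$restriction %||% "all"
    if (!cond$restriction %in% c("all", "preterm")) {
      abort(sprintf("condition `%s`: unknown restriction `%s`", nm,
                    cond$restriction),
            class = "neosurv_catalog_error")
    }
    if (!is.null(cond$severe_tokens) &&
        !all(cond$severe_tokens %in% cond$tokens)) {
      abort(sprintf("condition `%s`: severe_tokens must be a subset of tokens", nm),
            class = "neosurv_catalog_error")
    }
    catalog$conditions[[nm]] <- cond
  }
  structure(catalog, class = "condition_catalog")
}

catalog_tokens <- function(catalog) {
  unique(c(unlist(lapply(catalog$conditions, `[[`, "tokens"), use.names = FALSE),
           catalog$exclusions))
}

#' Read or write a condition catalog as YAML
#'
#' @param path File path.
#' @return `read_catalog()` returns a validated `condition_catalog`;
#'   `write_catalog()` returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  raw <- yaml::read_yaml(path)
  # yaml flattens named severity maps to lists; coerce back
  raw$conditions <- lapply(raw$conditions, function(cond) {
    cond$tokens <- as.character(unlist(cond$tokens))
    if (!is.null(cond$severe_tokens)) {
      cond$severe_tokens <- as.character(unlist(cond$severe_tokens))
    }
    if (!is.null(cond$severity)) cond$severity <- unlist(cond$severity)
    cond
  })
  raw$exclusions <- as.character(unlist(raw$exclusions))
  validate_catalog(raw)
}

#' @rdname read_catalog
#' @param catalog A `condition_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  catalog <- validate_catalog(catalog)
  yaml::write_yaml(unclass(catalog), path)
  invisible(path)
}

#' @export
print.condition_catalog <- function(x, ...) {
  cat("<condition_catalog>\n")
  for (nm in names(x$conditions)) {
    cond <- x$conditions[[nm]]
    restr <- if (cond$restriction != "all") sprintf(" [%s only]", cond$restriction) else ""
    cat(sprintf("  %s%s: %s\n", nm, restr, paste(cond$tokens, collapse = ", ")))
  }
  cat("  exclusions:", paste(x$exclusions, collapse = ", "), "\n")
  invisible(x)
}
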