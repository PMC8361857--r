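#' @keywords internal
"_PACKAGE"

## Fixed label sets used throughout. Category labels are uppercase strings;
## raw method/drug labels are lowercase.

#' Recognized category levels
#'
#' Fixed level sets for the coded exposure categories. `IMPLANT`, `DMPA`,
#' `OCP` are single-method categories; `MEC` groups other more-effective
#' methods (IUDs, permanent methods); `LEC` groups less-effective methods
#' (condoms, withdrawal/rhythm). ART categories follow the regimen
#' classification: anchor-drug classes (`EFV`, `NVP`, `PI`), `NRTI_ONLY`,
#' `COMBINATION` (two or more anchor classes), and `NO_ART`.
#'
#' @format Character vectors.
#' @name category-levels
NULL

#' @rdname category-levels
#' @export
CONTRACEPTIVE_LEVELS <- c("IMPLANT", "DMPA", "OCP", "MEC", "LEC", "NONE", "MISSING")

#' @rdname category-levels
#' @export
ART_LEVELS <- c("EFV", "NVP", "PI", "NRTI_ONLY", "COMBINATION", "NO_ART", "MISSING")

.contraceptive_labels <- list(
  MEC     = c("iud", "permanent"),
  IMPLANT = c("implant_etg", "implant_lng", "implant_unknown"),
  DMPA    = "dmpa",
  OCP     = "ocp",
  LEC     = c("condom", "natural"),
  NONE    = "none"
)

.art_anchor_labels <- list(
  EFV = "efavirenz",
  NVP = "nevirapine",
  PI  = c("lopinavir_r", "atazanavir_r", "darunavir_r", "nelfinavir", "indinavir")
)

.nrti_labels <- c("tenofovir", "lamivudine", "zidovudine", "abacavir",
                  "emtricitabine", "stavudine", "didanosine")

#' Assign a contraceptive category from recorded method labels
#'
#' Collapses the set of contraceptive methods documented at a visit into a
#' single category using the effectiveness hierarchy: MEC over implants over
#' DMPA over OCPs over LEC. An explicit empty set (no method documented as
#' used) maps to `NONE`; a value of `NA` (field not documented) maps to
#' `MISSING`; labels outside the recognized set are dropped with a warning
#' and, if nothing recognizable remains, the category is `MISSING`.
#'
#' @param codes Character vector of method labels for one visit (may be a
#'   single semicolon-delimited string, as stored in the visits CSV), or a
#'   list of such vectors for several visits.
#' @return A character scalar (or vector, for list input) among
#'   [CONTRACEPTIVE_LEVELS].
#' @examples
#' assign_contraceptive_category(c("implant_lng", "condom"))  # "IMPLANT"
#' assign_contraceptive_category(c("iud", "implant_etg", "dmpa"))  # "MEC"
#' assign_contraceptive_category(character(0))  # "NONE"
#' @export
assign_contraceptive_category <- function(codes) {
  if (is.list(codes)) {
    return(vapply(codes, assign_contraceptive_category, character(1)))
  }
  if (length(codes) == 1L && is.na(codes)) return("MISSING")
  codes <- unlist(strsplit(as.character(codes), ";", fixed = TRUE))
  codes <- codes[nzchar(codes)]
  if (length(codes) == 0L) return("NONE")
  known <- unlist(.contraceptive_labels, use.names = FALSE)
  bad <- setdiff(codes, known)
  if (length(bad)) {
    warning("unrecognized contraceptive label(s): ", paste(bad, collapse = ", "))
    codes <- setdiff(codes, bad)
    if (length(codes) == 0L) return("MISSING")
  }
  for (cat in c("MEC", "IMPLANT", "DMPA", "OCP", "LEC")) {
    if (any(codes %in% .contraceptive_labels[[cat]])) return(cat)
  }
  "NONE"
}

#' Assign an ART regimen category from recorded drug labels
#'
#' An ART regimen is defined as at least a three-drug antiretroviral
#' combination. An empty drug set maps to `NO_ART`; a documented but
#' incomplete set (one or two drugs) maps to `MISSING` rather than being
#' assumed untreated. Three or more drugs are classified by their anchor
#' drugs: exactly one of the efavirenz / nevirapine / protease-inhibitor
#' classes gives that class; two or more anchor classes give `COMBINATION`;
#' three or more NRTIs with no anchor give `NRTI_ONLY`.
#'
#' @param drugs Character vector of antiretroviral drug labels for one visit
#'   (or a single semicolon-delimited string, or a list of such for several
#'   visits).
#' @return A character scalar (or vector) among [ART_LEVELS].
#' @examples
#' assign_art_category(c("efavirenz", "tenofovir", "lamivudine"))  # "EFV"
#' assign_art_category(character(0))  # "NO_ART"
#' @export
assign_art_category <- function(drugs) {
  if (is.list(drugs)) {
    return(vapply(drugs, assign_art_category, character(1)))
  }
  if (length(drugs) == 1L && is.na(drugs)) return("MISSING")
  drugs <- unlist(strsplit(as.character(drugs), ";", fixed = TRUE))
  drugs <- unique(drugs[nzchar(drugs)])
  if (length(drugs) == 0L) return("NO_ART")
  if (length(drugs) < 3L) return("MISSING")
  anchors <- vapply(.art_anchor_labels, function(lab) any(drugs %in% lab), logical(1))
  n_anchor <- sum(anchors)
  if (n_anchor >= 2L) return("COMBINATION")
  if (n_anchor == 1L) return(names(.art_anchor_labels)[anchors])
  if (sum(drugs %in% .nrti_labels) >= 3L) return("NRTI_ONLY")
  "MISSING"
}

## Vectorized versions used by the cohort coder; identical rules, operating
## on a character column of semicolon-joined labels.
code_contraceptive_vec <- function(x) {
  ux <- unique(x)
  if (length(ux) < length(x)) return(code_contraceptive_vec(ux)[match(x, ux)])
  out <- character(length(x))
  out[] <- "NONE"
  out[is.na(x)] <- "MISSING"
  ok <- !is.na(x) & nzchar(x)
  if (!any(ok)) return(out)
  xs <- x[ok]
  hit <- function(labels) {
    pat <- paste0("(^|;)(", paste(labels, collapse = "|"), ")(;|$)")
    grepl(pat, xs)
  }
  res <- rep("NONE", length(xs))
  known_any <- hit(unlist(.contraceptive_labels, use.names = FALSE))
  ## rows carrying only unknown labels
  res[!known_any] <- "MISSING"
  if (any(!known_any)) {
    warning("unrecognized contraceptive label(s) in ", sum(!known_any),
            " visit(s); coded MISSING")
  }
  ## apply in ascending priority so the highest-priority hit wins
  for (cat in c("LEC", "OCP", "DMPA", "IMPLANT", "MEC")) {
    res[hit(.contraceptive_labels[[cat]])] <- cat
  }
  out[ok] <- res
  out
}

code_art_vec <- function(x) {
  ## visit tables repeat a small set of regimen strings; code unique values
  ## once and map back
  ux <- unique(x)
  if (length(ux) < length(x)) return(code_art_vec(ux)[match(x, ux)])
  out <- character(length(x))
  out[] <- "NO_ART"
  out[is.na(x)] <- "MISSING"
  ok <- !is.na(x) & nzchar(x)
  if (!any(ok)) return(out)
  parts <- strsplit(x[ok], ";", fixed = TRUE)
  out[ok] <- vapply(parts, function(drugs) {
    drugs <- unique(drugs[nzchar(drugs)])
    if (length(drugs) == 0L) return("NO_ART")
    if (length(drugs) < 3L) return("MISSING")
    anchors <- vapply(.art_anchor_labels, function(lab) any(drugs %in% lab), logical(1))
    n_anchor <- sum(anchors)
    if (n_anchor >= 2L) return("COMBINATION")
    if (n_anchor == 1L) return(names(.art_anchor_labels)[anchors])
    if (sum(drugs %in% .nrti_labels) >= 3L) return("NRTI_ONLY")
    "MISSING"
  }, character(1))
  out
}
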