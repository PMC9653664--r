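#' @keywords internal
#' @noRd
.sources <- c("MEG", "TG230", "NTP", "IARC", "JSOH", "NIOSH", "CPDB",
              "CCRIS", "DRUGBANK")

.norm_source <- function(source) {
  s <- toupper(trimws(source))
  if (!(s %in% .sources)) {
    stop(sprintf("unknown source '%s' (known: %s)", source,
                 paste(.sources, collapse = ", ")))
  }
  s
}

.norm_category <- function(category) toupper(trimws(as.character(category)))

.bad_category <- function(source, category) {
  stop(sprintf("unknown category '%s' for source %s", category, source))
}

#' Map a source-agency annotation to the binary carcinogenicity label
#'
#' Collapses each agency's category scheme onto class 1 (carcinogen) /
#' class 0 (non-carcinogen). Categories the agencies regard as not
#' classifiable or non-positive evidence (MEG D/E, IARC 3/4) are excluded
#' from the binary task rather than forced into a class.
#'
#' @param source one of MEG, TG230, NTP, IARC, JSOH, NIOSH, CPDB, CCRIS,
#'   DRUGBANK (case-insensitive).
#' @param category the agency's own code ("A", "2B", "known", ...).
#' @return 0, 1, or the string "excluded".
#' @examples
#' map_binary_label("IARC", "2B")        # 1
#' map_binary_label("DRUGBANK", "approved")  # 0
#' @export
map_binary_label <- function(source, category) {
  s <- .norm_source(source)
  cat <- .norm_category(category)
  switch(s,
    MEG = switch(cat, A = 1, B = 1, C = 1, D = "excluded", E = "excluded",
                 .bad_category(s, category)),
    TG230 = switch(cat, CARCINOGEN = 1, LISTED = 1,
                   .bad_category(s, category)),
    NTP = switch(cat, KNOWN = 1, `REASONABLY ANTICIPATED` = 1,
                 .bad_category(s, category)),
    IARC = switch(cat, `1` = 1, `2A` = 1, `2B` = 1,
                  `3` = "excluded", `4` = "excluded",
                  .bad_category(s, category)),
    JSOH = switch(cat, `1` = 1, `2A` = 1, `2B` = 1,
                  .bad_category(s, category)),
    NIOSH = switch(cat, CARCINOGEN = 1, LISTED = 1,
                   .bad_category(s, category)),
    CPDB = switch(cat, CARCINOGENIC = 1, NONCARCINOGENIC = 0,
                  .bad_category(s, category)),
    CCRIS = switch(cat, CARCINOGENIC = 1, MUTAGENIC = 1,
                   NONCARCINOGENIC = 0, NONMUTAGENIC = 0,
                   .bad_category(s, category)),
    DRUGBANK = switch(cat, APPROVED = 0, .bad_category(s, category)))
}

#' Map a source-agency annotation to the ternary carcinogenicity class
#'
#' Class 2 = carcinogens and probable carcinogens; class 1 = possible
#' carcinogens and not-classifiable chemicals; class 0 = non-carcinogens.
#' Only MEG, NTP, IARC, JSOH and CPDB annotations enter the ternary task.
#'
#' @inheritParams map_binary_label
#' @return 0, 1, 2, or "excluded".
#' @examples
#' map_multiclass_label("IARC", "3")  # 1
#' map_multiclass_label("MEG", "E")   # 0
#' @export
map_multiclass_label <- function(source, category) {
  s <- .norm_source(source)
  if (!(s %in% c("MEG", "NTP", "IARC", "JSOH", "CPDB"))) {
    stop(sprintf("source %s does not contribute to the ternary task", s))
  }
  cat <- .norm_category(category)
  switch(s,
    MEG = switch(cat, A = 2, B = 2, C = 1, D = 1, E = 0,
                 .bad_category(s, category)),
    NTP = switch(cat, KNOWN = 2, `REASONABLY ANTICIPATED` = 2,
                 .bad_category(s, category)),
    IARC = switch(cat, `1` = 2, `2A` = 2, `2B` = 1, `3` = 1,
                  `4` = "excluded", .bad_category(s, category)),
    JSOH = switch(cat, `1` = 2, `2A` = 2, `2B` = 1,
                  .bad_category(s, category)),
    CPDB = switch(cat, CARCINOGENIC = 2, NONCARCINOGENIC = 0,
                  .bad_category(s, category)))
}

#' Transform a TD50 dose into pTD50
#'
#' pTD50 is the base-10 logarithm of the inverse dose, `log10(1/td50)`:
#' the more potent the carcinogen (smaller TD50), the larger the pTD50.
#' The dose unit (mg/kg/day or mmol/kg/day) is carried by the caller; the
#' transform is unit-agnostic.
#'
#' @param td50 positive dose rate (vectorized).
#' @return pTD50 value(s).
#' @examples
#' td50_to_ptd50(0.01)  # 2
#' @export
td50_to_ptd50 <- function(td50) {
  if (any(!is.finite(td50)) || any(td50 <= 0)) {
    stop("TD50 must be a finite positive dose")
  }
  log10(1 / td50)
}

#' Harmonize a table of raw source annotations into chemical records
#'
#' Applies [map_binary_label()], [map_multiclass_label()] (where the
#' source participates) and [td50_to_ptd50()] row-wise. Excluded
#' annotations yield `NA` for that task.
#'
#' @param annotations data.frame with columns `id`, `smiles`, `source`,
#'   `category`, and optionally `td50` (positive dose or `NA`).
#' @return data.frame with one row per input annotation and columns `id`,
#'   `smiles`, `binary_label`, `multiclass_label`, `ptd50`.
#' @export
harmonize_annotations <- function(annotations) {
  stopifnot(all(c("id", "smiles", "source", "category") %in%
                  colnames(annotations)))
  n <- nrow(annotations)
  ternary_sources <- c("MEG", "NTP", "IARC", "JSOH", "CPDB")
  bin <- mc <- rep(NA_real_, n)
  ptd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    src <- .norm_source(annotations$source[i])
    b <- map_binary_label(src, annotations$category[i])
    if (!identical(b, "excluded")) bin[i] <- b
    if (src %in% ternary_sources) {
      m <- map_multiclass_label(src, annotations$category[i])
      if (!identical(m, "excluded")) mc[i] <- m
    }
    if ("td50" %in% colnames(annotations) && !is.na(annotations$td50[i])) {
      ptd[i] <- td50_to_ptd50(annotations$td50[i])
    }
  }
  data.frame(id = annotations$id, smiles = annotations$smiles,
             binary_label = bin, multiclass_label = mc, ptd50 = ptd,
             stringsAsFactors = FALSE)
}

#' Merge per-source records into one record per chemical
#'
#' Collapses duplicate identifiers. For each task independently, identical
#' labels collapse to that label; conflicting labels either drop the
#' chemical from that task (`conflict = "drop"`, the default, mirroring
#' the removal of conflicting chemicals during curation) or are resolved
#' by source priority (`conflict = "priority"`, first source in the
#' MEG, TG230, NTP, IARC, JSOH, NIOSH, CPDB, CCRIS, DRUGBANK order wins;
#' requires a `source` column).
#'
#' @param records data.frame as returned by [harmonize_annotations()]
#'   (columns `id`, `smiles`, `binary_label`, `multiclass_label`, `ptd50`;
#'   plus `source` when `conflict = "priority"`).
#' @param conflict "drop" or "priority".
#' @return data.frame with one row per identifier; a task's column is `NA`
#'   where no annotation labeled it or where a conflict was dropped.
#' @export
merge_and_deduplicate <- function(records, conflict = c("drop", "priority")) {
  conflict <- match.arg(conflict)
  if (conflict == "priority" && !("source" %in% colnames(records))) {
    stop("conflict = \"priority\" requires a source column")
  }
  collapse <- function(vals, prio) {
    vals_ok <- vals[!is.na(vals)]
    if (length(vals_ok) == 0L) return(NA_real_)
    u <- unique(vals_ok)
    if (length(u) == 1L) return(u)
    if (conflict == "drop") return(NA_real_)
    prio_ok <- prio[!is.na(vals)]
    vals_ok[order(prio_ok)][1]
  }
  ids <- unique(records$id)
  out <- data.frame(id = ids,
                    smiles = records$smiles[match(ids, records$id)],
                    binary_label = NA_real_, multiclass_label = NA_real_,
                    ptd50 = NA_real_, stringsAsFactors = FALSE)
  prio_all <- if (conflict == "priority") {
    match(toupper(trimws(records$source)), .sources)
  } else rep(1L, nrow(records))
  for (k in seq_along(ids)) {
    rows <- which(records$id == ids[k])
    out$binary_label[k] <- collapse(records$binary_label[rows], prio_all[rows])
    out$multiclass_label[k] <-
      collapse(records$multiclass_label[rows], prio_all[rows])
    out$ptd50[k] <- collapse(records$ptd50[rows], prio_all[rows])
  }
  out
}
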