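# Facility registry: inclusion filters and care-tier definitions applied to
# a raw facility table, producing the analysis sets (CT-equipped hospitals,
# stroke-ready hospitals, certified stroke units by class, thrombectomy
# centres).
#
# Filters:
#  * CT-equipped: >= 3 CT procedures in the reporting year, after
#    deduplication by (normalised name, coordinates rounded to 100 m);
#  * stroke-ready: >= 100 complex-stroke procedures (OPS 8-981 / 8-98b
#    style counts) OR certified stroke unit;
#  * certified stroke units carry a class: supraregional, regional or
#    telemedicine-supported regional (a subclass of regional).

su_class_levels <- c("supraregional", "regional", "telemedicine_regional",
                     "none")

validate_facility_table <- function(df) {
  need <- c("id", "name", "x", "y", "ct_procedures", "stroke_ops",
            "certified_su", "su_class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_invalid("facility table is missing columns: %s",
                 paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$ct_procedures < 0) || any(df$stroke_ops < 0))
    stop_invalid("procedure counts must be non-negative")
  if (!all(df$su_class %in% su_class_levels))
    stop_invalid("unknown su_class value(s): %s",
                 paste(setdiff(df$su_class, su_class_levels), collapse = ", "))
  bad <- df$su_class != "none" & !df$certified_su
  if (any(bad))
    stop_invalid("su_class set but certified_su FALSE for id(s): %s",
                 paste(df$id[bad], collapse = ", "))
  if (!"thrombectomy" %in% names(df)) df$thrombectomy <- FALSE
  invisible(df)
}

# Deduplication key: normalised name + coordinates rounded to 100 m.
dedup_key <- function(df) {
  nm <- tolower(gsub("\\s+", " ", trimws(df$name)))
  paste(nm, round(df$x / 100), round(df$y / 100), sep = "|")
}

#' Deduplicate a facility table
#'
#' Rows sharing a normalised name and coordinates rounded to 100 m are
#' collapsed to the first occurrence.
#'
#' @param df raw facility table.
#' @return deduplicated data.frame.
#' @export
dedup_facilities <- function(df) {
  df[!duplicated(dedup_key(df)), , drop = FALSE]
}

#' CT-equipped facility filter
#'
#' Ids of facilities documenting at least three CT procedures in the
#' reporting year, after deduplication.
#'
#' @param df raw facility table.
#' @return vector of facility ids.
#' @export
filter_ct_equipped <- function(df) {
  df <- validate_facility_table(df)
  if (nrow(df) == 0) return(df$id)
  df <- dedup_facilities(df)
  df$id[df$ct_procedures >= 3]
}

#' Stroke-ready facility filter
#'
#' Ids of facilities that billed at least 100 complex acute-stroke
#' procedures in the reporting year, or hold stroke-unit certification.
#'
#' @param df raw facility table.
#' @return vector of facility ids.
#' @export
classify_stroke_ready <- function(df) {
  df <- validate_facility_table(df)
  if (nrow(df) == 0) return(df$id)
  df <- dedup_facilities(df)
  df$id[df$stroke_ops >= 100 | df$certified_su]
}

#' Build a facility registry
#'
#' Applies deduplication, the CT and stroke-ready filters, and the tier
#' definitions, producing the seven analysis index sets. Tier nesting
#' (certified within stroke-ready within CT-equipped) is enforced: a
#' certified unit that fails the CT filter is clinically implausible, so by
#' default it is coerced into the larger sets with a warning listing the
#' offending ids; `on_nesting_violation = "fail"` errors instead.
#'
#' @param df raw facility table.
#' @param on_nesting_violation `"coerce"` (default) or `"fail"`.
#' @return object of class `facility_registry`: `$facilities` (deduplicated
#'   table) and `$sets`, a named list of id vectors `ct_equipped,
#'   stroke_ready, certified, supraregional, regional_or_tele, tele_only,
#'   thrombectomy`.
#' @export
build_registry <- function(df, on_nesting_violation = c("coerce", "fail")) {
  on_nesting_violation <- match.arg(on_nesting_violation)
  df <- validate_facility_table(df)
  if (!"thrombectomy" %in% names(df)) df$thrombectomy <- FALSE
  df <- dedup_facilities(df)
  certified <- df$id[df$certified_su]
  ct <- df$id[df$ct_procedures >= 3]
  ready <- df$id[df$stroke_ops >= 100 | df$certified_su]
  off_ct <- setdiff(certified, ct)
  if (length(off_ct)) {
    msg <- sprintf("certified stroke unit(s) failing the CT filter: %s",
                   paste(off_ct, collapse = ", "))
    if (on_nesting_violation == "fail") stop_invalid("%s", msg)
    warning(msg, " (coerced into CT-equipped set)", call. = FALSE)
    ct <- sort(union(ct, off_ct))
  }
  sets <- list(
    ct_equipped = ct,
    stroke_ready = ready,
    certified = certified,
    supraregional = df$id[df$su_class == "supraregional"],
    regional_or_tele = df$id[df$su_class %in% c("regional",
                                                "telemedicine_regional")],
    tele_only = df$id[df$su_class == "telemedicine_regional"],
    thrombectomy = df$id[as.logical(df$thrombectomy)])
  structure(list(facilities = df, sets = sets), class = "facility_registry")
}

#' @export
print.facility_registry <- function(x, ...) {
  cat("<facility_registry>\n")
  for (nm in names(x$sets))
    cat(sprintf("  %-17s %d\n", nm, length(x$sets[[nm]])))
  invisible(x)
}

#' Write a registry with derived membership columns
#'
#' @param registry a `facility_registry`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_registry_csv <- function(registry, path) {
  df <- registry$facilities
  for (nm in names(registry$sets))
    df[[paste0("in_", nm)]] <- df$id %in% registry$sets[[nm]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Facilities belonging to one registry set
#'
#' @param registry a `facility_registry`.
#' @param set a set name from `names(registry$sets)`.
#' @return the facility rows of that set (used to seed routing).
#' @export
registry_set_facilities <- function(registry, set) {
  if (!set %in% names(registry$sets))
    stop_invalid("unknown registry set '%s'", set)
  registry$facilities[registry$facilities$id %in% registry$sets[[set]], ,
                      drop = FALSE]
}
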