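#' RTI-relevant ICD-10 code set
#'
#' The default set of ICD-10 codes and code ranges that make a physician
#' contact eligible as a respiratory-tract-infection (RTI) index contact:
#' acute upper respiratory infections (J00-J06), influenza and pneumonia
#' (J10-J18), acute bronchitis (J20), unspecified acute lower respiratory
#' infection (J22), cough (R05), dyspnea (R06.0), fever (R50), unspecified
#' coronavirus infection (B34.2), viral infection of unspecified site (B39),
#' other infectious disease (B99), otitis media and mastoiditis (H65-H70),
#' COVID-19 (U07.1, U07.2) and the Swedish ICD-10-SE extension ZV100
#' (health-care intervention related to coronavirus infection).
#'
#' @return Character vector of code-or-range entries; each entry is either a
#'   single ICD-10 code (dotted or undotted) or a hyphenated range whose
#'   endpoints share the same letter prefix.
#' @seealso [compile_code_set()]
#' @export
rti_code_set <- function() {
  c("J00-J06", "J10-J18", "J20", "J22", "R05", "R06.0", "R50",
    "B34.2", "B39", "B99", "H65-H70", "U07.1", "U07.2", "ZV100")
}

#' Normalize ICD-10 codes
#'
#' Uppercases and strips dots and whitespace, so `"J06.9"` and `"j069"`
#' compare equal.  Registries mix the dotted and undotted dialects.
#'
#' @param codes character vector of diagnosis codes.
#' @return Normalized character vector (same length).
#' @export
normalize_icd <- function(codes) {
  toupper(gsub("[.[:space:]]", "", as.character(codes)))
}

#' Compile a code-set specification into matchable prefixes
#'
#' Ranges such as `"J00-J06"` are expanded to every 3-character code they
#' span (inclusive).  Matching is by prefix on normalized codes: a listed
#' 3-character code covers all its decimal children (J20 covers J20.9), and
#' a listed 4-character code such as R06.0 covers R06.0 and deeper
#' subdivisions but not its siblings (R06.1 does not match).  National
#' extension codes (e.g. ZV100) are matched as literal prefixes; no
#' validation against the WHO ICD-10 ontology is attempted.
#'
#' @param entries character vector of codes and ranges; defaults to
#'   [rti_code_set()].
#' @return An object of class `rti_code_set` with elements `entries` (the
#'   input) and `prefixes` (unique normalized prefixes).
#' @examples
#' cs <- compile_code_set(c("J00-J06", "R06.0"))
#' is_rti_relevant(c("J069"), cs)   # TRUE  (child of J06)
#' is_rti_relevant(c("R06.1"), cs)  # FALSE (sibling of R06.0)
#' @export
compile_code_set <- function(entries = rti_code_set()) {
  if (!is.character(entries)) stop("code set entries must be a character vector")
  prefixes <- character(0)
  for (e in entries) {
    n <- normalize_icd(e)
    if (grepl("-", n, fixed = TRUE)) {
      parts <- strsplit(n, "-", fixed = TRUE)[[1]]
      if (length(parts) != 2L || !all(grepl("^[A-Z][0-9]{2}$", parts))) {
        stop(sprintf(
          "malformed range entry '%s': endpoints must be a letter plus two digits", e))
      }
      if (substr(parts[1], 1, 1) != substr(parts[2], 1, 1)) {
        stop(sprintf("malformed range entry '%s': endpoints use different letters", e))
      }
      a <- as.integer(substr(parts[1], 2, 3))
      b <- as.integer(substr(parts[2], 2, 3))
      if (a > b) stop(sprintf("malformed range entry '%s': start exceeds end", e))
      prefixes <- c(prefixes, sprintf("%s%02d", substr(parts[1], 1, 1), a:b))
    } else {
      if (n == "" || !grepl("^[A-Z]+[0-9]+$", n)) {
        stop(sprintf("malformed code entry '%s'", e))
      }
      prefixes <- c(prefixes, n)
    }
  }
  structure(list(entries = entries, prefixes = unique(prefixes)),
            class = "rti_code_set")
}

#' @export
print.rti_code_set <- function(x, ...) {
  cat("<rti_code_set>", length(x$entries), "entries,",
      length(x$prefixes), "compiled prefixes\n")
  invisible(x)
}

#' Vectorized code-set membership
#'
#' @param codes character vector of diagnosis codes (possibly `NA` or `""`;
#'   unparseable codes simply never match).
#' @param codeset a compiled [rti_code_set][compile_code_set()].
#' @return Logical vector: does each code equal or descend from a compiled
#'   prefix?
#' @export
matches_code_set <- function(codes, codeset) {
  stopifnot(inherits(codeset, "rti_code_set"))
  x <- normalize_icd(codes)
  u <- unique(x)
  m <- logical(length(u))
  for (p in codeset$prefixes) m <- m | startsWith(u, p)
  m[is.na(u) | u == ""] <- FALSE
  m[match(x, u)]
}

#' Is a contact RTI-relevant?
#'
#' A contact qualifies if at least one of its registered diagnoses, after
#' normalization, equals or descends from a code in the compiled set.  An
#' empty diagnosis list (no registered diagnosis) never qualifies.
#'
#' @param diagnoses character vector of 0-8 ICD-10 codes for one contact.
#' @param codeset a compiled [rti_code_set][compile_code_set()].
#' @return Single logical.
#' @export
is_rti_relevant <- function(diagnoses, codeset) {
  length(diagnoses) > 0L && any(matches_code_set(diagnoses, codeset))
}

#' RTI relevance for each row of a contact table
#'
#' Applies [matches_code_set()] across the `diag1..diag8` columns.
#'
#' @param contacts data.frame/data.table with the contact schema.
#' @param codeset a compiled [rti_code_set][compile_code_set()].
#' @return Logical vector, one element per row.
#' @export
rti_flags <- function(contacts, codeset) {
  dt <- as.data.table(contacts)
  cols <- intersect(DIAG_COLS, names(dt))
  if (length(cols) == 0L) stop("contact table has no diag1..diag8 columns")
  out <- logical(nrow(dt))
  for (cl in cols) out <- out | matches_code_set(dt[[cl]], codeset)
  out
}
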