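#' Construct a code set
#'
#' A code set is the basic matching unit of the algorithm: a collection of
#' codes from one coding system, matched either exactly or by prefix
#' (prefix matching reflects hierarchical systems such as ICD, where
#' `"C50"` covers all breast-cancer subsites `"C500"`, `"C501"`, ...).
#'
#' Codes are normalized to upper case and trimmed on construction.
#' Duplicates are dropped with a warning.  In prefix mode, a set in which
#' one code is a prefix of another is rejected: the shorter code already
#' covers everything the longer one would, so the pair is ambiguous and
#' almost always a curation error.
#'
#' @param codes Character vector of codes (non-empty after normalization).
#' @param code_system Label of the coding system (e.g. `"ICD10-SYN"`).
#' @param match_mode `"exact"` (default) or `"prefix"`.
#' @return An object of class `sbce_code_set`.
#' @examples
#' cs <- code_set(c("C50", "C79"), "ICD10-SYN", match_mode = "prefix")
#' match_code("C509", cs)
#' @export
code_set <- function(codes, code_system, match_mode = c("exact", "prefix")) {
  match_mode <- match.arg(match_mode)
  stopifnot(is.character(codes), is.character(code_system),
            length(code_system) == 1L)
  codes <- toupper(trimws(as.character(codes)))
  codes <- codes[nzchar(codes)]
  if (anyDuplicated(codes)) {
    dup <- unique(codes[duplicated(codes)])
    warn(paste0("Dropping duplicate code(s) in ", code_system, " set: ",
                paste(dup, collapse = ", ")))
    codes <- unique(codes)
  }
  if (length(codes) == 0L) {
    abort("A code set must contain at least one code.")
  }
  if (match_mode == "prefix" && length(codes) > 1L) {
    for (i in seq_along(codes)) {
      hit <- codes[-i][startsWith(codes[-i], codes[i])]
      if (length(hit)) {
        abort(paste0(
          "Ambiguous prefix pair in ", code_system, " set: \"", codes[i],
          "\" is a prefix of \"", hit[1L], "\"."))
      }
    }
  }
  structure(
    list(code_system = code_system, match_mode = match_mode,
         codes = sort(codes)),
    class = "sbce_code_set")
}

#' Match codes against a code set
#'
#' Vectorized over `code`.  Exact mode tests set membership; prefix mode
#' tests whether any member of the set is a prefix of the code.  Codes are
#' normalized (upper case, trimmed) before matching, mirroring
#' [code_set()].  A code from a different coding system never matches:
#' pass the event's `code_system` to enforce this.
#'
#' @param code Character vector of codes to test.
#' @param code_set An [code_set()] object.
#' @param code_system Optional character vector (recycled) naming the
#'   system each `code` belongs to; when supplied, codes whose system
#'   differs from the set's return `FALSE`.
#' @return Logical vector, one element per `code`.
#' @export
match_code <- function(code, code_set, code_system = NULL) {
  stopifnot(inherits(code_set, "sbce_code_set"))
  code <- toupper(trimws(as.character(code)))
  out <- if (code_set$match_mode == "exact") {
    code %in% code_set$codes
  } else {
    vapply(code, function(x) {
      !is.na(x) && any(startsWith(x, code_set$codes))
    }, logical(1), USE.NAMES = FALSE)
  }
  out[is.na(code) | !nzchar(code)] <- FALSE
  if (!is.null(code_system)) {
    out <- out & !is.na(code_system) & code_system == code_set$code_system
  }
  out
}

new_criterion_definition <- function(criterion_id, sources, code_sets) {
  if (!criterion_id %in% criterion_ids()) {
    abort(paste0("Unknown criterion id: ", criterion_id))
  }
  bad <- setdiff(sources, event_sources())
  if (length(bad)) {
    abort(paste0("Unknown source(s) for criterion ", criterion_id, ": ",
                 paste(bad, collapse = ", ")))
  }
  structure(
    list(criterion_id = criterion_id,
         sources = sources,
         code_sets = code_sets,
         laterality_capable =
           criterion_id %in% laterality_capable_criteria()),
    class = "sbce_criterion")
}

parse_code_set_block <- function(block, where) {
  need <- c("code_system", "codes")
  miss <- setdiff(need, names(block))
  if (length(miss)) {
    abort(paste0("Code set ", where, " is missing field(s): ",
                 paste(miss, collapse = ", ")))
  }
  code_set(codes = unlist(block$codes),
           code_system = block$code_system,
           match_mode = block$match_mode %||% "exact")
}

#' Read an algorithm code-list file
#'
#' The four criteria that define a second breast cancer event (death from
#' breast cancer; procedure with associated diagnosis; systemic treatment;
#' radiotherapy) are driven entirely by configurable code lists, since the
#' codes that operationalize each criterion depend on the jurisdiction's
#' coding systems.  This reads a YAML file with one block per criterion
#' (see the packaged example and `codelists_schema.yaml` in `extdata`).
#'
#' The `procedure_diagnosis` criterion requires two sets —
#' `procedure_codes` and `diagnosis_codes` — because it fires only when a
#' single event carries both a matching procedure code and a matching
#' associated diagnosis code.  The other criteria take a single `codes`
#' block (pooled across their sources) or a map from source to code-set.
#'
#' @param path Path to a YAML code-list file.
#' @return An object of class `sbce_codelists`: a list with `criteria`
#'   (one [code_set()]-backed definition per criterion) and `provenance`.
#' @seealso [sbce_example_codelists()] for the packaged synthetic lists.
#' @export
read_codelists <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Code-list file not found: ", path))
  }
  raw <- yaml::read_yaml(path)
  crit_blocks <- raw$criteria
  if (is.null(crit_blocks)) {
    abort("Code-list file has no `criteria` block.")
  }
  miss <- setdiff(criterion_ids(), names(crit_blocks))
  if (length(miss)) {
    abort(paste0("Code-list file is missing criterion definition(s): ",
                 paste(miss, collapse = ", ")))
  }
  criteria <- lapply(criterion_ids(), function(cid) {
    block <- crit_blocks[[cid]]
    sources <- unlist(block$sources)
    if (is.null(sources)) {
      abort(paste0("Criterion ", cid, " lists no sources."))
    }
    sets <- if (cid == "procedure_diagnosis") {
      list(
        procedure = parse_code_set_block(
          block$procedure_codes,
          paste0("`procedure_codes` of ", cid)),
        diagnosis = parse_code_set_block(
          block$diagnosis_codes,
          paste0("`diagnosis_codes` of ", cid)))
    } else if (!is.null(block$codes$code_system)) {
      # one pooled set for all of the criterion's sources
      list(pooled = parse_code_set_block(block$codes,
                                         paste0("`codes` of ", cid)))
    } else {
      sets <- lapply(names(block$codes), function(src) {
        parse_code_set_block(block$codes[[src]],
                             paste0("source ", src, " of ", cid))
      })
      setNames(sets, names(block$codes))
    }
    new_criterion_definition(cid, sources, sets)
  })
  structure(
    list(criteria = setNames(criteria, criterion_ids()),
         provenance = raw$provenance %||% "unspecified"),
    class = "sbce_codelists")
}

#' Path to the packaged synthetic code lists
#'
#' The package ships a synthetic, non-clinical set of code lists used by
#' the examples, the test fixtures and the cohort generator.  The codes
#' are invented stand-ins with ICD-like structure; they carry no clinical
#' validity and must be replaced with curated lists before any use on
#' real data.
#'
#' @return Path to `codelists_synthetic.yaml`.
#' @export
sbce_example_codelists <- function() {
  system.file("extdata", "codelists_synthetic.yaml", package = "sbce",
              mustWork = TRUE)
}

#' @export
print.sbce_codelists <- function(x, ...) {
  cat("<sbce_codelists>  provenance:", x$provenance, "\n")
  for (cr in x$criteria) {
    n_codes <- sum(vapply(cr$code_sets, function(s) length(s$codes),
                          integer(1)))
    cat(sprintf("  %-20s sources: %-40s codes: %d%s\n",
                cr$criterion_id,
                paste(cr$sources, collapse = ","),
                n_codes,
                if (cr$laterality_capable) "  [lateralized]" else ""))
  }
  invisible(x)
}

#' @export
print.sbce_code_set <- function(x, ...) {
  cat(sprintf("<code_set> %s (%s): %s\n", x$code_system, x$match_mode,
              paste(x$codes, collapse = ", ")))
  invisible(x)
}
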