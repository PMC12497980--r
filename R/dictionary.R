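# Drug name normalization and event (preferred-term) definitions.

#' Build a drug dictionary
#'
#' Maps free-text drug names to normalized generic names via synonym
#' lists (brand names, spelling variants). Matching elsewhere is
#' case-insensitive substring matching after punctuation stripping, so
#' synonyms should be full words. Loading fails if one synonym maps to
#' two different drugs.
#'
#' @param drugs data.frame with columns `drug` (generic name), `class`
#'   (pharmacological class label), `synonyms` (";"-separated string, may
#'   be empty).
#' @return object of class `drug_dictionary`.
#' @seealso [ici_dictionary()] for the bundled checkpoint-inhibitor set.
#' @export
drug_dictionary <- function(drugs) {
  stopifnot(all(c("drug", "class", "synonyms") %in% names(drugs)))
  drugs$drug <- tolower(trimws(drugs$drug))
  if (anyDuplicated(drugs$drug))
    stop("drug names must be unique after case folding")
  syn <- lapply(seq_len(nrow(drugs)), function(i) {
    s <- c(drugs$drug[i], strsplit(drugs$synonyms[i], ";")[[1]])
    unique(normalize_drugname(s[nzchar(trimws(s))]))
  })
  flat <- unlist(syn)
  owner <- rep(drugs$drug, lengths(syn))
  dup <- flat[duplicated(flat)]
  clash <- unique(flat[flat %in% dup &
                         ave(seq_along(flat), flat,
                             FUN = function(i) length(unique(owner[i]))) > 1])
  if (length(clash))
    stop("synonym(s) mapped to more than one drug: ",
         paste(clash, collapse = ", "))
  structure(list(drugs = drugs$drug, classes = setNames(drugs$class, drugs$drug),
                 synonyms = setNames(syn, drugs$drug)),
            class = "drug_dictionary")
}

#' @export
print.drug_dictionary <- function(x, ...) {
  cat("drug dictionary:", length(x$drugs), "drugs\n")
  for (d in x$drugs)
    cat(sprintf("  %s (%s): %s\n", d, x$classes[[d]],
                paste(x$synonyms[[d]], collapse = ", ")))
  invisible(x)
}

# uppercase, strip punctuation to spaces, squeeze whitespace
normalize_drugname <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("[^A-Z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Bundled immune-checkpoint-inhibitor dictionary
#'
#' The seven marketed checkpoint inhibitors commonly screened in
#' spontaneous-report studies, with their major brand names: anti-PD-L1
#' atezolizumab (Tecentriq), durvalumab (Imfinzi), avelumab (Bavencio);
#' anti-PD-1 tislelizumab (Tevimbra/Baizean), pembrolizumab (Keytruda),
#' nivolumab (Opdivo); anti-CTLA-4 ipilimumab (Yervoy). User-extensible
#' via [drug_dictionary()] or [read_drug_dictionary()].
#'
#' @return a `drug_dictionary`.
#' @export
ici_dictionary <- function() {
  drug_dictionary(data.frame(
    drug = c("atezolizumab", "durvalumab", "avelumab", "tislelizumab",
             "pembrolizumab", "nivolumab", "ipilimumab"),
    class = c("PD-L1 inhibitor", "PD-L1 inhibitor", "PD-L1 inhibitor",
              "PD-1 inhibitor", "PD-1 inhibitor", "PD-1 inhibitor",
              "CTLA-4 inhibitor"),
    synonyms = c("Tecentriq", "Imfinzi", "Bavencio", "Tevimbra;Baizean",
                 "Keytruda", "Opdivo", "Yervoy"),
    stringsAsFactors = FALSE
  ))
}

#' Read a drug dictionary or event definition from a YAML config
#'
#' The drug dictionary file is a list of entries with keys `drug`,
#' `class`, `synonyms` (list). The event file has keys `name` and `pts`
#' (list of MedDRA preferred terms).
#'
#' @param path YAML file path.
#' @return a `drug_dictionary` resp. `event_definition`.
#' @export
read_drug_dictionary <- function(path) {
  entries <- yaml::read_yaml(path)
  drug_dictionary(data.frame(
    drug = vapply(entries, `[[`, "", "drug"),
    class = vapply(entries, function(e) e$class %||% "unclassified", ""),
    synonyms = vapply(entries, function(e)
      paste(unlist(e$synonyms), collapse = ";"), ""),
    stringsAsFactors = FALSE
  ))
}

#' @rdname read_drug_dictionary
#' @export
read_event_definition <- function(path) {
  cfg <- yaml::read_yaml(path)
  event_definition(cfg$name, unlist(cfg$pts))
}

#' Define an adverse event as a set of MedDRA preferred terms
#'
#' Matching against reaction rows is case-insensitive exact PT equality.
#'
#' @param name short event label.
#' @param pts non-empty character vector of preferred terms.
#' @return object of class `event_definition`.
#' @export
event_definition <- function(name, pts) {
  pts <- unique(trimws(pts))
  pts <- pts[nzchar(pts)]
  if (!length(pts)) stop("pt list must be non-empty")
  structure(list(name = name, pts = pts), class = "event_definition")
}

#' @export
print.event_definition <- function(x, ...) {
  cat("event '", x$name, "': ", length(x$pts), " preferred terms\n",
      sep = "")
  invisible(x)
}

#' Default pancreatitis event definition
#'
#' Pancreatitis preferred terms reported as signal-positive in FAERS
#' checkpoint-inhibitor screens plus the common pancreatitis PTs; fully
#' overridable because published PT screens differ.
#'
#' @return an `event_definition`.
#' @export
pancreatitis_event <- function() {
  event_definition("pancreatitis", c(
    "Pancreatitis", "Pancreatitis acute", "Pancreatitis chronic",
    "Immune-mediated pancreatitis", "Autoimmune pancreatitis",
    "Obstructive pancreatitis", "Pancreatitis necrotising",
    "Oedematous pancreatitis", "Pancreatitis haemorrhagic"
  ))
}

#' Match free-text drug names against a dictionary
#'
#' Case-insensitive, punctuation-stripped substring match of each
#' dictionary synonym inside the verbatim drug name; the active
#' ingredient field (`prod_ai`) is consulted only where the drug name
#' fails to match.
#'
#' @param drugname character vector of verbatim drug names.
#' @param prod_ai optional character vector of active-ingredient strings.
#' @param dict a `drug_dictionary`.
#' @return character vector of normalized drug names (`NA` where no
#'   match).
#' @export
#' @examples
#' match_drug(c("OPDIVO", "KEYTRUDA 200MG", "aspirin"), dict = ici_dictionary())
match_drug <- function(drugname, prod_ai = NULL, dict) {
  stopifnot(inherits(dict, "drug_dictionary"))
  match_one_field <- function(x) {
    xn <- paste0(" ", normalize_drugname(x), " ")
    out <- rep(NA_character_, length(x))
    for (d in dict$drugs) {
      for (s in dict$synonyms[[d]]) {
        hit <- is.na(out) & grepl(s, xn, fixed = TRUE)
        out[hit] <- d
      }
    }
    out
  }
  out <- match_one_field(drugname)
  if (!is.null(prod_ai)) {
    miss <- is.na(out) & !is.na(prod_ai) & nzchar(prod_ai)
    if (any(miss)) out[miss] <- match_one_field(prod_ai[miss])
  }
  out
}
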