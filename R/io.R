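# FAERS quarterly ASCII dialect: "$"-delimited text, one header line,
# five tables per quarter (DEMO, DRUG, REAC, THER, OUTC).

.faers_kinds <- c("demo", "drug", "reac", "ther", "outc")

# mandatory columns per table kind; sex has a legacy alias (gndr_cod)
.faers_columns <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age",
           "age_cod", "wt", "wt_cod", "occp_cod", "reporter_country"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  reac = c("primaryid", "pt"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
  outc = c("primaryid", "outc_cod")
)

#' Read one FAERS quarterly ASCII table
#'
#' Reads a "$"-delimited FAERS table file (header line of column names,
#' Latin-1-compatible byte text). Column names are lower-cased and legacy
#' aliases resolved (`gndr_cod` for `sex`, `outc_code` for `outc_cod`).
#' Rows without a `primaryid` are rejected, never fatal; rejected rows are
#' attached as the `"rejected"` attribute with a reason.
#'
#' @param path file path.
#' @param kind one of `"demo"`, `"drug"`, `"reac"`, `"ther"`, `"outc"`.
#' @return data.frame of character columns (at least the mandatory
#'   columns for `kind`), with attribute `"rejected"`.
#' @export
read_faers_table <- function(path, kind) {
  kind <- match.arg(tolower(kind), .faers_kinds)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = "$", header = TRUE, quote = "",
                           comment.char = "", colClasses = "character",
                           stringsAsFactors = FALSE, fill = TRUE,
                           fileEncoding = "latin1", check.names = FALSE,
                           blank.lines.skip = TRUE)
  names(raw) <- tolower(names(raw))
  # legacy column aliases across FAERS eras
  alias <- c(gndr_cod = "sex", outc_code = "outc_cod", isr = "primaryid")
  for (old in names(alias)) {
    if (old %in% names(raw) && !(alias[[old]] %in% names(raw)))
      names(raw)[names(raw) == old] <- alias[[old]]
  }
  missing_cols <- setdiff(.faers_columns[[kind]], names(raw))
  if (length(missing_cols))
    stop("table '", kind, "' is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- is.na(raw$primaryid) | raw$primaryid == ""
  rejected <- raw[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$reject_reason <- "missing primaryid"
  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Read a directory of FAERS quarterly files
#'
#' Locates quarter file sets named like `DEMO23Q1.txt` ... `OUTC23Q1.txt`
#' and row-binds each table kind across quarters.
#'
#' @param dir directory containing the quarterly files.
#' @param quarters optional character vector of quarter labels
#'   (`"2023Q1"` style) to restrict to.
#' @return a `faers_data` object: named list of the five tables.
#' @export
read_faers <- function(dir, quarters = NULL) {
  demo_files <- list.files(dir, pattern = "^DEMO[0-9]{2}Q[1-4]\\.txt$")
  if (!length(demo_files)) stop("no DEMO??Q?.txt files found in ", dir)
  suffixes <- sub("^DEMO", "", demo_files)
  if (!is.null(quarters)) {
    keep <- paste0(substr(quarters, 3, 4), substr(quarters, 5, 6), ".txt")
    suffixes <- intersect(suffixes, keep)
  }
  suffixes <- sort(suffixes)
  tabs <- lapply(.faers_kinds, function(kind) {
    parts <- lapply(suffixes, function(sfx) {
      path <- file.path(dir, paste0(toupper(kind), sfx))
      if (!file.exists(path))
        stop("incomplete quarter set: expected ", path)
      read_faers_table(path, kind)
    })
    do.call(rbind, parts)
  })
  names(tabs) <- .faers_kinds
  faers_data(tabs)
}

#' Construct a faers_data container
#'
#' @param tables named list with elements `demo`, `drug`, `reac`, `ther`,
#'   `outc` (character data.frames in the FAERS dialect).
#' @return object of class `faers_data`.
#' @export
faers_data <- function(tables) {
  stopifnot(all(.faers_kinds %in% names(tables)))
  for (kind in .faers_kinds) {
    missing_cols <- setdiff(.faers_columns[[kind]], names(tables[[kind]]))
    if (length(missing_cols))
      stop("table '", kind, "' is missing mandatory column(s): ",
           paste(missing_cols, collapse = ", "))
  }
  structure(tables[.faers_kinds], class = "faers_data")
}

#' @export
print.faers_data <- function(x, ...) {
  cat("FAERS-dialect dataset\n")
  for (kind in .faers_kinds)
    cat(sprintf("  %s: %d rows\n", toupper(kind), nrow(x[[kind]])))
  invisible(x)
}

#' Write FAERS tables as quarterly "$"-delimited files
#'
#' Splits the dataset into quarters by the DEMO `fda_dt` receipt date and
#' writes the five tables per quarter as `DEMOyyQq.txt` etc. An empty
#' table yields a file holding only the header line.
#'
#' @param x a `faers_data` object.
#' @param dir output directory (created if needed).
#' @return invisible character vector of the file paths written.
#' @export
write_faers <- function(x, dir) {
  stopifnot(inherits(x, "faers_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pd <- parse_faers_date(x$demo$fda_dt)
  q <- ifelse(is.na(pd$year) | is.na(pd$month), "unknown",
              paste0(pd$year, "Q", (pd$month - 1) %/% 3 + 1))
  quarters <- sort(unique(q))
  paths <- character(0)
  for (qq in quarters) {
    ids <- x$demo$primaryid[q == qq]
    sfx <- if (qq == "unknown") "00Q0" else
      paste0(substr(qq, 3, 4), substr(qq, 5, 6))
    for (kind in .faers_kinds) {
      tab <- x[[kind]]
      tab <- tab[tab$primaryid %in% ids, , drop = FALSE]
      path <- file.path(dir, paste0(toupper(kind), sfx, ".txt"))
      utils::write.table(tab, path, sep = "$", quote = FALSE,
                         row.names = FALSE, fileEncoding = "latin1")
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

# ---- unit conversions ------------------------------------------------------

# FAERS age units to years
.age_factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.143,
                 DY = 1 / 365.25)

#' Convert FAERS age and weight fields to standard units
#'
#' Age codes: `DEC` (decades, x10), `YR`, `MON` (/12), `WK` (/52.143),
#' `DY` (/365.25). Weight codes: `KG`/`KGS`, `LBS` (x0.45359237), `GMS`
#' (/1000). Unknown units, unparseable values and out-of-range results
#' (age outside \[0, 120\], weight outside (0, 500)) give `NA`; the row is
#' kept.
#'
#' @param value character or numeric vector of raw values.
#' @param unit character vector of unit codes.
#' @return numeric vector (years resp. kilograms).
#' @export
#' @examples
#' age_to_years(2, "DEC")        # 20
#' weight_to_kg(154, "LBS")      # 69.85 (to 2 decimals)
age_to_years <- function(value, unit) {
  v <- num(value)
  f <- .age_factor[toupper(trimws(as.character(unit)))]
  out <- v * unname(f)
  out[!is.na(out) & (out < 0 | out > 120)] <- NA_real_
  out
}

#' @rdname age_to_years
#' @export
weight_to_kg <- function(value, unit) {
  v <- num(value)
  f <- c(KG = 1, KGS = 1, LBS = 0.45359237,
         GMS = 0.001)[toupper(trimws(as.character(unit)))]
  out <- v * unname(f)
  out[!is.na(out) & (out <= 0 | out >= 500)] <- NA_real_
  out
}

# FAERS reporter occupation codes
.occp_map <- c(MD = "physician", PH = "pharmacist",
               HP = "health_professional", CN = "consumer",
               LW = "lawyer", OT = "other", RN = "health_professional")

#' Parse a DEMO table into analysis-ready report records
#'
#' Normalizes demographics: sex to `male`/`female`/`NA`, age to years,
#' weight to kg, reporter occupation to a closed vocabulary
#' (unmapped codes become `other`, absent becomes `NA`), and derives the
#' receipt-year. Raw date strings are retained for downstream partial-date
#' policies.
#'
#' @param demo DEMO data.frame from [read_faers_table()].
#' @return data.frame of report records, one row per DEMO row.
#' @export
parse_reports <- function(demo) {
  sex_raw <- toupper(trimws(demo$sex))
  sex <- ifelse(sex_raw == "M", "male",
                ifelse(sex_raw == "F", "female", NA_character_))
  occ_raw <- toupper(trimws(demo$occp_cod))
  occupation <- ifelse(occ_raw == "", NA_character_,
                       ifelse(occ_raw %in% names(.occp_map),
                              .occp_map[occ_raw], "other"))
  country <- trimws(demo$reporter_country)
  country[country == ""] <- NA_character_
  fda <- parse_faers_date(demo$fda_dt)
  data.frame(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    fda_dt = demo$fda_dt,
    event_dt = demo$event_dt,
    year = fda$year,
    sex = sex,
    age_years = age_to_years(demo$age, demo$age_cod),
    weight_kg = weight_to_kg(demo$wt, demo$wt_cod),
    occupation = unname(occupation),
    country = country,
    stringsAsFactors = FALSE
  )
}

#' Deduplicate spontaneous reports
#'
#' FAERS carries multiple versions of one case; the convention is to keep,
#' per `caseid`, the record with the latest `fda_dt` receipt date. When
#' receipt dates tie, the largest numeric `primaryid` (the later-assigned
#' identifier) wins, which makes the rule deterministic.
#'
#' @param reports data.frame of report records (from [parse_reports()]);
#'   any data.frame with `caseid`, `primaryid`, `fda_dt` columns works.
#' @return the retained rows, in original order, with attribute
#'   `"removed"` giving the number of rows dropped.
#' @export
dedup_reports <- function(reports) {
  if (!nrow(reports)) {
    attr(reports, "removed") <- 0L
    return(reports)
  }
  fd <- num(reports$fda_dt)
  fd[is.na(fd)] <- -Inf
  pid <- num(reports$primaryid)
  pid[is.na(pid)] <- -Inf
  o <- order(fd, pid, decreasing = TRUE)
  ranked <- reports[o, , drop = FALSE]
  keep_pid <- ranked$primaryid[!duplicated(ranked$caseid)]
  out <- reports[reports$primaryid %in% keep_pid, , drop = FALSE]
  # identical (caseid, primaryid) rows are pathological; keep the first
  out <- out[!duplicated(out$caseid), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- nrow(reports) - nrow(out)
  out
}
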