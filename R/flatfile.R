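#' Detect the flat-file format from the file extension
#'
#' The input format is identified purely by the file ending: `.embl` for
#' EMBL-formatted and `.gb` for GenBank-formatted flat files. Matching is
#' case-insensitive on the extension; any other ending is rejected.
#'
#' @param path Path to (or name of) the input flat file.
#' @return `"embl"` or `"genbank"`.
#' @examples
#' detect_flatfile_format("example_trnKmatK.embl")
#' detect_flatfile_format("records.GB")
#' @export
detect_flatfile_format <- function(path) {
  if (!is.character(path) || length(path) != 1L || !nzchar(path))
    stop_usage("input path must be a single non-empty filename")
  ext <- tolower(tools::file_ext(path))
  if (ext == "embl") return("embl")
  if (ext == "gb") return("genbank")
  stop_usage(sprintf(
    "unsupported file extension on '%s': accepted endings are '.embl' and '.gb'",
    path))
}

#' Parse a feature-table location string
#'
#' Supports the location constructs needed for barcoding records: plain
#' intervals `"a..b"`, single bases `"a"`, `complement(...)` and
#' `join(...)`. A `<` before a start coordinate marks the feature as
#' 5'-partial and a `>` before an end coordinate as 3'-partial; under
#' `complement()` the two markers are mirrored, because the written low
#' coordinate is then the biological 3' end. `order(...)` and remote
#' (accession-qualified) references are rejected.
#'
#' @param text Location string as written in the flat file.
#' @param seq_len Length of the owning record's sequence; all coordinates
#'   must lie in `[1, seq_len]`.
#' @return A `feature_location`: list with `intervals` (data frame of
#'   1-based inclusive `start`/`end`), `strand` (`"+"` or `"-"`),
#'   `partial5` and `partial3` flags.
#' @examples
#' parse_location("38..620", 650)
#' parse_location("<1..620", 650)$partial5
#' parse_location("complement(10..20)", 650)$strand
#' @export
parse_location <- function(text, seq_len) {
  raw <- gsub("\\s+", "", text)
  if (!nzchar(raw)) stop_record("empty feature location")
  if (grepl("order(", raw, fixed = TRUE))
    stop_record(sprintf("unsupported location construct 'order(...)' in '%s'", text))
  if (grepl(":", raw, fixed = TRUE))
    stop_record(sprintf("remote location references are not supported: '%s'", text))

  strand <- "+"
  inner <- raw
  if (grepl("^complement\\(", inner)) {
    strand <- "-"
    inner <- sub("^complement\\((.*)\\)$", "\\1", inner)
  }
  if (grepl("^join\\(", inner))
    inner <- sub("^join\\((.*)\\)$", "\\1", inner)
  if (grepl("[()]", inner))
    stop_record(sprintf("unparseable feature location '%s'", text))

  parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
  if (!length(parts)) stop_record(sprintf("unparseable feature location '%s'", text))

  single <- "^(<?)([0-9]+)$"
  interval <- "^(<?)([0-9]+)\\.\\.(>?)([0-9]+)$"
  starts <- ends <- integer(length(parts))
  p_low <- p_high <- FALSE
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (grepl(interval, p)) {
      m <- regmatches(p, regexec(interval, p))[[1]]
      starts[i] <- as.integer(m[[3]])
      ends[i] <- as.integer(m[[5]])
      if (i == 1L) p_low <- m[[2]] == "<"
      if (i == length(parts)) p_high <- m[[4]] == ">"
    } else if (grepl(single, p)) {
      m <- regmatches(p, regexec(single, p))[[1]]
      starts[i] <- ends[i] <- as.integer(m[[3]])
      if (i == 1L) p_low <- m[[2]] == "<"
    } else {
      stop_record(sprintf("unparseable feature location '%s'", text))
    }
  }

  if (any(starts > ends))
    stop_record(sprintf("location start exceeds end in '%s'", text))
  if (any(starts < 1L) || any(ends > seq_len))
    stop_record(sprintf(
      "location '%s' lies outside the sequence bounds [1, %d]", text, seq_len))
  if (length(parts) > 1L && any(starts[-1L] <= ends[-length(ends)]))
    stop_record(sprintf("location segments overlap or are unordered in '%s'", text))

  structure(
    list(
      intervals = data.frame(start = starts, end = ends),
      strand = strand,
      partial5 = if (strand == "+") p_low else p_high,
      partial3 = if (strand == "+") p_high else p_low
    ),
    class = "feature_location"
  )
}

loc_start <- function(loc) min(loc$intervals$start)
loc_end <- function(loc) max(loc$intervals$end)

new_feature <- function(key, location, location_text, qualifiers) {
  structure(
    list(key = key, location = location, location_text = location_text,
         qualifiers = qualifiers),
    class = "insdc_feature"
  )
}

#' Qualifier values of a feature
#'
#' @param feature An `insdc_feature`.
#' @param name Qualifier name.
#' @return Character vector of all values stored under `name` (possibly
#'   length zero); repeated qualifiers are preserved in order.
#' @export
qualifier_values <- function(feature, name) {
  q <- feature$qualifiers
  unname(q[names(q) == name])
}

new_seq_record <- function(record_id, organism, sequence, features,
                           issues = character()) {
  structure(
    list(record_id = record_id, organism = organism, sequence = sequence,
         features = features, issues = issues),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s | %s | %d bp | %d features\n",
              x$record_id, x$organism %||% "<no organism>",
              nchar(x$sequence), length(x$features)))
  for (f in x$features)
    cat(sprintf("  %-14s %s\n", f$key, f$location_text))
  invisible(x)
}

# Shared feature-table accumulator. `contents` are the feature-table lines
# with their leading format prefix removed, so that a new feature starts in
# column 1 and continuations are indented. Returns a list of raw features
# (key, location text, qualifier lines collapsed).
collect_features <- function(contents, entry_label) {
  feats <- list()
  cur <- NULL
  flush <- function() if (!is.null(cur)) feats[[length(feats) + 1L]] <<- cur
  for (ln in contents) {
    if (grepl("^\\S", ln)) {
      flush()
      key <- sub("\\s.*$", "", ln)
      rest <- trimws(sub("^\\S+", "", ln))
      cur <- list(key = key, loc = rest, quals = character())
    } else {
      ln <- trimws(ln)
      if (!nzchar(ln)) next
      if (is.null(cur))
        stop_parse(sprintf("feature continuation before any feature in %s",
                           entry_label))
      if (startsWith(ln, "/")) {
        cur$quals <- c(cur$quals, ln)
      } else if (length(cur$quals)) {
        # wrapped qualifier value
        n <- length(cur$quals)
        cur$quals[n] <- paste(cur$quals[n], ln)
      } else {
        # wrapped location
        cur$loc <- paste0(cur$loc, ln)
      }
    }
  }
  flush()
  feats
}

parse_qualifier_lines <- function(lines, entry_label) {
  out <- character()
  pat <- "^/([A-Za-z0-9_]+)(=(.*))?$"
  for (ln in lines) {
    if (!grepl(pat, ln))
      stop_parse(sprintf("malformed qualifier line '%s' in %s", ln, entry_label))
    m <- regmatches(ln, regexec(pat, ln))[[1]]
    val <- if (nzchar(m[[3]])) m[[4]] else ""
    val <- sub("^\"", "", sub("\"$", "", val))
    out <- c(out, stats::setNames(val, m[[2]]))
  }
  out
}

# Turn raw feature descriptors into insdc_feature values; location-parsing
# problems are recorded as per-record issues, not parse aborts.
build_features <- function(raw, seq_len, entry_label) {
  issues <- character()
  feats <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    rf <- raw[[i]]
    quals <- parse_qualifier_lines(rf$quals, entry_label)
    loc <- tryCatch(parse_location(rf$loc, seq_len),
                    fw_record_error = function(e) e)
    if (inherits(loc, "error")) {
      issues <- c(issues,
                  sprintf("feature %d (%s): %s", i, rf$key, conditionMessage(loc)))
      loc <- NULL
    }
    feats[[i]] <- new_feature(rf$key, loc, rf$loc, quals)
  }
  list(features = feats, issues = issues)
}

finish_record <- function(record_id, raw_feats, seq_lines, declared_len,
                          entry_label) {
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence))
    stop_parse(sprintf("%s contains no sequence", entry_label))
  if (!grepl("^[ACGTN]*$", sequence))
    stop_parse(sprintf("%s contains non-nucleotide sequence characters",
                       entry_label))
  if (!is.na(declared_len) && nchar(sequence) != declared_len)
    stop_parse(sprintf(
      "%s declares %d bp but its sequence block holds %d letters",
      entry_label, declared_len, nchar(sequence)))

  built <- build_features(raw_feats, nchar(sequence), entry_label)
  feats <- built$features
  organism <- NA_character_
  if (length(feats) && feats[[1L]]$key == "source") {
    org <- qualifier_values(feats[[1L]], "organism")
    if (length(org) && nzchar(org[[1L]])) organism <- org[[1L]]
  }
  new_seq_record(record_id, organism, sequence, feats, built$issues)
}

parse_entry_embl <- function(lines, entry_no) {
  label <- sprintf("EMBL entry %d", entry_no)
  is_id <- startsWith(lines, "ID ")
  is_ft <- startsWith(lines, "FT")
  if (!any(is_id))
    stop_parse(sprintf("%s lacks an ID line", label))
  id_i <- which(is_id)[[1L]]
  if (any(which(is_ft) < id_i))
    stop_parse(sprintf("%s has a feature table before its ID header", label))

  id_line <- trimws(sub("^ID", "", lines[[id_i]]))
  record_id <- sub("[;\\s].*$", "", id_line, perl = TRUE)
  label <- sprintf("EMBL entry %d (%s)", entry_no, record_id)
  m <- regmatches(id_line, regexec("([0-9]+)\\s+BP", id_line, ignore.case = TRUE))[[1]]
  declared <- if (length(m)) as.integer(m[[2]]) else NA_integer_

  sq_i <- which(startsWith(lines, "SQ"))
  if (!length(sq_i))
    stop_parse(sprintf("%s lacks an SQ sequence block", label))
  sq_i <- sq_i[[1L]]
  seq_lines <- lines[seq.int(sq_i + 1L, length.out = length(lines) - sq_i)]

  ft_contents <- substring(lines[is_ft], 6L)
  raw <- collect_features(ft_contents, label)
  finish_record(record_id, raw, seq_lines, declared, label)
}

parse_entry_genbank <- function(lines, entry_no) {
  label <- sprintf("GenBank entry %d", entry_no)
  locus_i <- which(startsWith(lines, "LOCUS"))
  feat_i <- which(startsWith(lines, "FEATURES"))
  if (!length(locus_i))
    stop_parse(sprintf("%s lacks a LOCUS line", label))
  locus_i <- locus_i[[1L]]
  if (length(feat_i) && feat_i[[1L]] < locus_i)
    stop_parse(sprintf("%s has a feature table before its LOCUS header", label))

  toks <- strsplit(trimws(sub("^LOCUS", "", lines[[locus_i]])), "\\s+")[[1]]
  record_id <- if (length(toks)) toks[[1L]] else ""
  label <- sprintf("GenBank entry %d (%s)", entry_no, record_id)
  m <- regmatches(lines[[locus_i]],
                  regexec("([0-9]+)\\s+bp", lines[[locus_i]], ignore.case = TRUE))[[1]]
  declared <- if (length(m)) as.integer(m[[2]]) else NA_integer_

  origin_i <- which(startsWith(lines, "ORIGIN"))
  if (!length(origin_i))
    stop_parse(sprintf("%s lacks an ORIGIN sequence block", label))
  origin_i <- origin_i[[1L]]
  seq_lines <- lines[seq.int(origin_i + 1L, length.out = length(lines) - origin_i)]

  raw <- list()
  if (length(feat_i)) {
    ft_lines <- lines[seq.int(feat_i[[1L]] + 1L, origin_i - 1L)]
    ft_lines <- ft_lines[!grepl("^(BASE COUNT|CONTIG)", ft_lines)]
    raw <- collect_features(substring(ft_lines, 6L), label)
  }
  finish_record(record_id, raw, seq_lines, declared, label)
}

#' Read a multi-record EMBL or GenBank flat file
#'
#' Parses every `//`-terminated entry of the file into a `seq_record`:
#' record identifier, organism (from the source feature's `organism`
#' qualifier), the uppercased, un-interleaved DNA sequence, and the ordered
#' feature table with parsed locations. Only the feature table and the
#' sequence are interpreted; description and reference lines are ignored.
#'
#' Structural defects of the file (missing ID/LOCUS header, feature table
#' before the header, sequence length disagreeing with the declared length,
#' content after the last `//` terminator, empty input) abort parsing with
#' an error naming the offending entry. A location string that cannot be
#' interpreted is recorded in the owning record's `issues` field and later
#' handled as a per-record audit failure rather than a parse abort.
#'
#' @param path Path to the flat file.
#' @param format `"embl"` or `"genbank"`; defaults to extension-based
#'   detection via [detect_flatfile_format()].
#' @return List of `seq_record` objects in file order.
#' @export
read_flatfile <- function(path, format = detect_flatfile_format(path)) {
  format <- match.arg(format, c("embl", "genbank"))
  if (!file.exists(path))
    stop_parse(sprintf("input file not found: %s", path))
  lines <- readLines(path, warn = FALSE)

  term <- which(trimws(lines) == "//")
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank))
    stop_parse(sprintf("no sequence records found in %s (file is empty)", path))
  if (!length(term) || max(nonblank) > max(term))
    stop_parse(sprintf(
      "malformed entry delimiter in %s: content is not terminated by '//'", path))

  parse_one <- switch(format, embl = parse_entry_embl, genbank = parse_entry_genbank)
  records <- list()
  start <- 1L
  entry_no <- 0L
  for (t in term) {
    chunk <- lines[seq.int(start, t - 1L)]
    start <- t + 1L
    if (!any(nzchar(trimws(chunk)))) next
    entry_no <- entry_no + 1L
    records[[entry_no]] <- parse_one(chunk, entry_no)
  }
  if (!entry_no)
    stop_parse(sprintf("no sequence records found in %s", path))
  records
}
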