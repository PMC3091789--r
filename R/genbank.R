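# GenBank flat-file reader/writer (the subset needed for annotated
# bacterial replicons: LOCUS, CDS features with locus_tag / product /
# translation qualifiers, ORIGIN sequence). No installed package parses
# GenBank flat files, so the subset is implemented here.

parseLocation <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- 1L
  if (startsWith(loc, "complement(")) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (startsWith(loc, "join(")) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  pieces <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  parts <- t(vapply(pieces, function(p) {
    se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    if (length(se) == 1L) se <- c(se, se)
    se
  }, integer(2)))
  # GenBank 1-based inclusive -> 0-based half-open
  cbind(parts[, 1L] - 1L, parts[, 2L], deparse.level = 0)[, , drop = FALSE] ->
    parts01
  list(start = min(parts01[, 1L]), end = max(parts01[, 2L]),
       strand = strand, parts = parts01)
}

parseQualifiers <- function(lines) {
  txt <- paste(sub("^ {21}", "", lines), collapse = "\n")
  starts <- gregexpr("(^|\n)/[A-Za-z_]+=?", txt)[[1L]]
  if (starts[1L] == -1L) return(list())
  chunks <- character(length(starts))
  for (i in seq_along(starts)) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1L] - 1L else nchar(txt)
    chunks[i] <- gsub("^\n", "", substr(txt, from, to))
  }
  quals <- list()
  for (ch in chunks) {
    key <- sub("^/([A-Za-z_]+).*$", "\\1", ch)
    val <- sub("^/[A-Za-z_]+=?", "", ch)
    val <- gsub("\n", "", val)
    val <- gsub("^\"|\"$", "", val)
    # translations are wrapped across lines without separators
    if (key == "translation") val <- gsub("[[:space:]]", "", val)
    quals[[key]] <- val
  }
  quals
}

parseOneGenBank <- function(lines) {
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank record: no LOCUS line")
  toks <- strsplit(trimws(locus[1L]), "[[:space:]]+")[[1L]]
  name <- toks[2L]
  topo <- if (any(toks == "circular")) "circular" else "linear"
  accLine <- grep("^ACCESSION", lines, value = TRUE)
  acc <- if (length(accLine)) {
    a <- strsplit(trimws(accLine[1L]), "[[:space:]]+")[[1L]]
    if (length(a) >= 2L) a[2L] else name
  } else name

  oi <- grep("^ORIGIN", lines)
  if (!length(oi)) stop("GenBank record ", acc, " has no ORIGIN sequence")
  seqLines <- lines[(oi[1L] + 1L):length(lines)]
  seqLines <- seqLines[!grepl("^//", seqLines)]
  dna <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  if (!nzchar(dna)) stop("GenBank record ", acc, " has an empty sequence")
  dna <- DNAString(dna)

  fi <- grep("^FEATURES", lines)
  featRows <- list()
  if (length(fi)) {
    block <- lines[(fi[1L] + 1L):(oi[1L] - 1L)]
    isNew <- grepl("^ {5}\\S", block)
    idx <- which(isNew)
    autoTag <- 0L
    for (k in seq_along(idx)) {
      from <- idx[k]
      to <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
      head <- block[from]
      key <- sub("^ {5}(\\S+).*$", "\\1", head)
      if (key != "CDS") next
      body <- block[seq(from, to)]
      # location may continue onto lines that do not start a qualifier
      qstart <- grep("^ {21}/", body)
      locEnd <- if (length(qstart)) qstart[1L] - 1L else length(body)
      loc <- paste(c(sub("^ {5}\\S+\\s+", "", body[1L]),
                     trimws(body[seq_len(locEnd)][-1L])), collapse = "")
      locp <- try(parseLocation(loc), silent = TRUE)
      if (inherits(locp, "try-error")) {
        warning("skipping CDS with unparseable location: ", loc)
        next
      }
      if (locp$start < 0L || locp$end > length(dna)) {
        warning("skipping CDS with out-of-range coordinates: ", loc)
        next
      }
      quals <- if (length(qstart))
        parseQualifiers(body[qstart[1L]:length(body)]) else list()
      autoTag <- autoTag + 1L
      tag <- quals$locus_tag %||% sprintf("CDS_%04d", autoTag)
      tr <- quals$translation %||% NA_character_
      if (is.na(tr) || !nzchar(tr))
        tr <- translateCDS(dna, locp$start, locp$end, locp$strand,
                           parts = locp$parts)
      featRows[[length(featRows) + 1L]] <- list(
        locus_tag = tag, start = locp$start, end = locp$end,
        strand = locp$strand, translation = tr,
        product = quals$product %||% NA_character_)
    }
  }
  feats <- if (length(featRows)) {
    DataFrame(
      locus_tag = vapply(featRows, `[[`, character(1), "locus_tag"),
      start = vapply(featRows, `[[`, numeric(1), "start"),
      end = vapply(featRows, `[[`, numeric(1), "end"),
      strand = vapply(featRows, `[[`, numeric(1), "strand"),
      translation = vapply(featRows, `[[`, character(1), "translation"),
      product = vapply(featRows, `[[`, character(1), "product"))
  } else NULL
  GenomeRecord(acc, dna, feats, topology = topo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a GenBank flat file
#'
#' Parses one or more records (separated by `//`) from a GenBank flat file.
#' Resolves `complement()` and `join()` locations; CDS features without a
#' `/translation` qualifier are translated from their coordinates; features
#' with out-of-range coordinates are skipped with a warning.
#'
#' @param path file path.
#' @return a single [GenomeRecord-class] if the file holds one record,
#'   otherwise a list of them (one per contig).
#' @export
readGenBank <- function(path) {
  lines <- readLines(path)
  recEnds <- grep("^//", lines)
  if (!length(recEnds)) recEnds <- length(lines)
  recStarts <- c(1L, utils::head(recEnds, -1L) + 1L)
  recs <- list()
  for (i in seq_along(recEnds)) {
    chunk <- lines[recStarts[i]:recEnds[i]]
    if (!any(grepl("^LOCUS", chunk))) next
    recs[[length(recs) + 1L]] <- parseOneGenBank(chunk)
  }
  if (!length(recs)) stop("no GenBank records found in ", path)
  if (length(recs) == 1L) recs[[1L]] else recs
}

#' Write a GenomeRecord as a GenBank flat file
#'
#' Emits LOCUS/ACCESSION headers, one CDS feature per annotated gene (with
#' `/locus_tag`, `/product`, `/translation`), and the ORIGIN sequence.
#' Output is deterministic (fixed date stamp) so identical records produce
#' byte-identical files.
#'
#' @param g a [GenomeRecord-class] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(g, path) {
  if (is(g, "GenomeRecord")) g <- list(g)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (rec in g) {
    L <- length(rec)
    wl <- function(...) writeLines(paste0(...), con)
    wl(sprintf("LOCUS       %-16s %11d bp    DNA     %-8s BCT 01-JAN-2000",
               accession(rec), L, topology(rec)))
    wl("DEFINITION  synthetic annotated replicon.")
    wl(sprintf("ACCESSION   %s", accession(rec)))
    wl("FEATURES             Location/Qualifiers")
    wl(sprintf("     source          1..%d", L))
    f <- features(rec)
    for (i in seq_len(nrow(f))) {
      loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
      if (f$strand[i] < 0L) loc <- sprintf("complement(%s)", loc)
      wl(sprintf("     CDS             %s", loc))
      wl(sprintf("                     /locus_tag=\"%s\"", f$locus_tag[i]))
      prod <- f$product[i]
      if (!is.na(prod))
        wl(sprintf("                     /product=\"%s\"", prod))
      tr <- f$translation[i]
      if (!is.na(tr) && nzchar(tr)) {
        txt <- paste0("/translation=\"", tr, "\"")
        first <- substr(txt, 1L, 58L)
        rest <- substring(txt, 59L)
        wl("                     ", first)
        while (nzchar(rest)) {
          wl("                     ", substr(rest, 1L, 58L))
          rest <- substring(rest, 59L)
        }
      }
    }
    wl("ORIGIN")
    s <- tolower(as.character(genomeSequence(rec)))
    pos <- seq(1L, nchar(s), by = 60L)
    for (p in pos) {
      chunk <- substr(s, p, min(p + 59L, nchar(s)))
      groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      wl(sprintf("%9d %s", p, paste(groups, collapse = " ")))
    }
    wl("//")
  }
  invisible(path)
}
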