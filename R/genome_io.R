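# Genome input: GenBank flat files (with CDS annotation) and plain FASTA.
#
# Internal coordinates are 0-based half-open everywhere; all user-facing
# coordinates (queries, CSV output) are 1-based inclusive as in GenBank.
# No GenBank parser ships with the installed R stack, so a focused flat-file
# reader (LOCUS/FEATURES/ORIGIN, CDS features with locus_tag/gene/protein_id/
# codon_start qualifiers, complement/join locations) is implemented here.

#' Construct a genome record
#'
#' @param contig_id contig identifier.
#' @param sequence DNA string; normalised to uppercase A/C/G/T/N (other
#'   IUPAC codes become N with a warning).
#' @param features list of [gene_feature()] objects.
#' @return an object of class `GenomeRecord`.
#' @export
genome_record <- function(contig_id, sequence, features = list()) {
  sequence <- normalise_sequence(sequence, contig_id)
  n <- nchar(sequence)
  if (n == 0) {
    bescan_abort(sprintf("contig '%s' has an empty sequence", contig_id),
                 "bescan_format_error")
  }
  for (f in features) {
    if (any(f$intervals[, 1] < 0) || any(f$intervals[, 2] > n)) {
      bescan_abort(
        sprintf("feature interval outside contig '%s' (length %d)",
                contig_id, n),
        "bescan_format_error"
      )
    }
  }
  structure(
    list(contig_id = contig_id, sequence = sequence, length = n,
         features = features),
    class = "GenomeRecord"
  )
}

#' Construct a CDS feature
#'
#' @param intervals two-column matrix of 0-based half-open `(start, end)`
#'   genomic intervals, ordered and non-overlapping.
#' @param strand `"+"` or `"-"`.
#' @param locus_tag,gene_name,protein_id optional qualifiers (`NA` if absent).
#' @param codon_start_offset 0, 1 or 2 bases skipped before the first codon.
#' @return an object of class `GeneFeature`.
#' @export
gene_feature <- function(intervals, strand,
                         locus_tag = NA_character_,
                         gene_name = NA_character_,
                         protein_id = NA_character_,
                         codon_start_offset = 0L) {
  intervals <- matrix(as.integer(intervals), ncol = 2)
  if (nrow(intervals) > 1) {
    o <- order(intervals[, 1])
    intervals <- intervals[o, , drop = FALSE]
    if (any(intervals[-1, 1] < intervals[-nrow(intervals), 2])) {
      bescan_abort("feature intervals overlap", "bescan_format_error")
    }
  }
  if (any(intervals[, 1] >= intervals[, 2])) {
    bescan_abort("feature interval with start >= end", "bescan_format_error")
  }
  if (!strand %in% c("+", "-")) {
    bescan_abort("strand must be '+' or '-'", "bescan_argument_error")
  }
  structure(
    list(locus_tag = locus_tag, gene_name = gene_name,
         protein_id = protein_id, strand = strand, intervals = intervals,
         codon_start_offset = as.integer(codon_start_offset)),
    class = "GeneFeature"
  )
}

# Preferred display/reference name of a feature.
feature_ref <- function(feature, index = NA_integer_) {
  feature$locus_tag %||% feature$gene_name %||% feature$protein_id %||%
    paste0("feature_", index)
}

get_record <- function(records, contig_id) {
  for (r in records) if (r$contig_id == contig_id) return(r)
  bescan_abort(sprintf("unknown contig '%s'", contig_id),
               "bescan_not_found_error")
}

# Sequence of a contig as seen 5'->3' on the requested strand.
strand_seq <- function(record, strand) {
  if (strand == "+") record$sequence else revcomp(record$sequence)
}

# ---------------------------------------------------------------------------
# GenBank location strings

# Parse "123..456", "complement(join(1..9,13..21))", "<1..300", "42" into
# list(strand=, intervals=matrix 0-based half-open).  Fuzzy bounds (< >) are
# truncated to their concrete coordinates with a warning.
parse_gb_location <- function(loc) {
  s <- gsub("[[:space:]]", "", loc)
  if (grepl("[<>]", s)) {
    warning(sprintf("fuzzy location '%s' truncated to concrete bounds", loc),
            call. = FALSE)
    s <- gsub("[<>]", "", s)
  }
  parse_node <- function(x) {
    if (grepl("^complement\\(", x)) {
      inner <- parse_node(sub("\\)$", "", sub("^complement\\(", "", x)))
      inner$strand <- if (inner$strand == "+") "-" else "+"
      return(inner)
    }
    if (grepl("^(join|order)\\(", x)) {
      body <- sub("\\)$", "", sub("^(join|order)\\(", "", x))
      parts <- character(0)
      depth <- 0L
      last <- 1L
      cs <- chars(body)
      for (i in seq_along(cs)) {
        if (cs[i] == "(") depth <- depth + 1L
        if (cs[i] == ")") depth <- depth - 1L
        if (cs[i] == "," && depth == 0L) {
          parts <- c(parts, substr(body, last, i - 1L))
          last <- i + 1L
        }
      }
      parts <- c(parts, substr(body, last, nchar(body)))
      nodes <- lapply(parts, parse_node)
      strands <- unique(vapply(nodes, `[[`, "", "strand"))
      if (length(strands) != 1) {
        bescan_abort(sprintf("mixed-strand location '%s' not supported", loc),
                     "bescan_format_error")
      }
      return(list(
        strand = strands,
        intervals = do.call(rbind, lapply(nodes, `[[`, "intervals"))
      ))
    }
    if (grepl("^[0-9]+\\.\\.[0-9]+$", x)) {
      ab <- as.numeric(strsplit(x, "..", fixed = TRUE)[[1]])
      return(list(strand = "+",
                  intervals = matrix(c(ab[1] - 1, ab[2]), ncol = 2)))
    }
    if (grepl("^[0-9]+$", x)) {
      a <- as.numeric(x)
      return(list(strand = "+", intervals = matrix(c(a - 1, a), ncol = 2)))
    }
    bescan_abort(sprintf("cannot parse GenBank location '%s'", loc),
                 "bescan_format_error")
  }
  parse_node(s)
}

# ---------------------------------------------------------------------------
# GenBank reading

#' Read an annotated genome from a GenBank flat file
#'
#' Parses every record of a GenBank flat file, capturing the contig
#' sequence and all `CDS` features with their `locus_tag`, `gene`,
#' `protein_id` and `codon_start` qualifiers.  Sequences are uppercased and
#' ambiguity codes other than N are mapped to N with a warning.
#'
#' @param path path to a GenBank file.
#' @return list of [genome_record()] objects, in file order.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) {
    bescan_abort(sprintf("no such file: %s", path), "bescan_format_error")
  }
  lines <- readLines(path, warn = FALSE)
  locus_at <- grep("^LOCUS", lines)
  if (length(locus_at) == 0) {
    bescan_abort(sprintf("'%s' does not look like GenBank (no LOCUS line)",
                         path), "bescan_format_error")
  }
  ends <- grep("^//\\s*$", lines)
  records <- list()
  for (ri in seq_along(locus_at)) {
    from <- locus_at[ri]
    to <- ends[ends > from][1]
    if (is.na(to)) to <- length(lines)
    records[[ri]] <- parse_genbank_record(lines[from:to])
  }
  records
}

parse_genbank_record <- function(lines) {
  locus_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  contig_id <- if (length(locus_fields) >= 2) locus_fields[2] else "unknown"

  feat_at <- grep("^FEATURES", lines)
  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0) {
    bescan_abort(sprintf("record '%s' has no ORIGIN sequence", contig_id),
                 "bescan_empty_sequence_error")
  }
  origin_at <- origin_at[1]

  seq_lines <- lines[(origin_at + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- paste(gsub("[0-9[:space:]]", "", seq_lines), collapse = "")
  if (nchar(sequence) == 0) {
    bescan_abort(sprintf("record '%s' has an empty sequence", contig_id),
                 "bescan_empty_sequence_error")
  }

  features <- list()
  if (length(feat_at) > 0 && origin_at > feat_at[1] + 1) {
    ftab <- lines[(feat_at[1] + 1):(origin_at - 1)]
    features <- parse_feature_table(ftab)
  }
  genome_record(contig_id, sequence, features)
}

parse_feature_table <- function(ftab) {
  # Group the feature table into (key, location, qualifiers) blocks.
  entries <- list()
  cur <- NULL
  for (line in ftab) {
    if (grepl("^ {5}\\S", line) && !grepl("^ {21}", line)) {
      if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
      parts <- strsplit(trimws(line), "\\s+")[[1]]
      cur <- list(key = parts[1],
                  location = paste(parts[-1], collapse = ""),
                  quals = character(0))
    } else if (!is.null(cur)) {
      txt <- trimws(line)
      if (startsWith(txt, "/")) {
        cur$quals <- c(cur$quals, txt)
      } else if (length(cur$quals) > 0) {
        # continuation of a (possibly quoted) qualifier value
        cur$quals[length(cur$quals)] <-
          paste0(cur$quals[length(cur$quals)], txt)
      } else {
        cur$location <- paste0(cur$location, txt)
      }
    }
  }
  if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur

  qual_value <- function(quals, name) {
    pat <- paste0("^/", name, "=")
    hit <- grep(pat, quals, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    v <- sub(pat, "", hit[1])
    gsub("^\"|\"$", "", v)
  }

  feats <- list()
  for (e in entries) {
    if (e$key != "CDS") next
    loc <- parse_gb_location(e$location)
    cs <- qual_value(e$quals, "codon_start")
    offset <- if (is.na(cs)) 0L else as.integer(cs) - 1L
    feats[[length(feats) + 1L]] <- gene_feature(
      intervals = loc$intervals,
      strand = loc$strand,
      locus_tag = qual_value(e$quals, "locus_tag"),
      gene_name = qual_value(e$quals, "gene"),
      protein_id = qual_value(e$quals, "protein_id"),
      codon_start_offset = offset
    )
  }
  feats
}

# ---------------------------------------------------------------------------
# GenBank writing (fixture output and round-trip tests)

format_gb_location <- function(feature) {
  iv <- feature$intervals
  parts <- sprintf("%d..%d", iv[, 1] + 1L, iv[, 2])
  loc <- if (length(parts) == 1) parts else
    paste0("join(", paste(parts, collapse = ","), ")")
  if (feature$strand == "-") loc <- paste0("complement(", loc, ")")
  loc
}

#' Write genome records to a GenBank flat file
#'
#' Minimal writer used by the synthetic fixture generator and round-trip
#' tests; emits LOCUS, FEATURES (source + CDS) and ORIGIN sections.
#'
#' @param records list of [genome_record()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(records, path) {
  out <- character(0)
  for (r in records) {
    out <- c(out, sprintf(
      "LOCUS       %s %d bp    DNA     linear   SYN 01-JAN-2026",
      r$contig_id, r$length
    ))
    out <- c(out, "DEFINITION  synthetic fixture genome.",
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", r$length))
    for (f in r$features) {
      out <- c(out, sprintf("     CDS             %s", format_gb_location(f)))
      if (!is.na(f$locus_tag))
        out <- c(out, sprintf("                     /locus_tag=\"%s\"",
                              f$locus_tag))
      if (!is.na(f$gene_name))
        out <- c(out, sprintf("                     /gene=\"%s\"",
                              f$gene_name))
      if (!is.na(f$protein_id))
        out <- c(out, sprintf("                     /protein_id=\"%s\"",
                              f$protein_id))
      out <- c(out, sprintf("                     /codon_start=%d",
                            f$codon_start_offset + 1L))
    }
    out <- c(out, "ORIGIN")
    seq <- tolower(r$sequence)
    starts <- seq(1L, r$length, by = 60L)
    for (s in starts) {
      line <- substr(seq, s, min(s + 59L, r$length))
      blocks <- substring(line, seq(1, nchar(line), 10),
                          pmin(seq(10, nchar(line) + 9, 10), nchar(line)))
      out <- c(out, sprintf("%9d %s", s, paste(blocks, collapse = " ")))
    }
    out <- c(out, "//")
  }
  writeLines(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# FASTA

#' Read a genome from a FASTA file
#'
#' Records carry no features; base-editor codon annotation is impossible in
#' sequence-only mode.
#'
#' @param path path to a FASTA file.
#' @return list of [genome_record()] objects with empty feature lists.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    bescan_abort(sprintf("no such file: %s", path), "bescan_format_error")
  }
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) {
                   bescan_abort(sprintf("cannot parse FASTA '%s': %s",
                                        path, conditionMessage(e)),
                                "bescan_format_error")
                 })
  if (length(ss) == 0) {
    bescan_abort(sprintf("FASTA '%s' contains no records", path),
                 "bescan_format_error")
  }
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1)
  lapply(seq_along(ss), function(i) {
    genome_record(ids[i], as.character(ss[[i]]))
  })
}

# ---------------------------------------------------------------------------
# Target resolution

#' Construct a target region
#'
#' @param contig_id contig identifier.
#' @param start,end 0-based half-open bounds.
#' @param source_query the user query that produced the region.
#' @return an object of class `TargetRegion`.
#' @export
target_region <- function(contig_id, start, end, source_query = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end) {
    bescan_abort("invalid target region bounds", "bescan_bounds_error")
  }
  structure(list(contig_id = contig_id, start = start, end = end,
                 source_query = source_query),
            class = "TargetRegion")
}

#' Resolve a user target query to a genomic region
#'
#' Accepts either a 1-based inclusive coordinate range `"START-END"`
#' (optionally prefixed `"contig:START-END"` when the genome has several
#' contigs; `START == END` denotes a single base) or a string matching
#' exactly one feature's gene name, locus tag or protein ID, in which case
#' the feature's genomic envelope is returned.
#'
#' @param records list of [genome_record()] objects.
#' @param query query string.
#' @return a [target_region()].
#' @export
resolve_target <- function(records, query) {
  query <- trimws(query)
  m <- regmatches(query,
                  regexec("^(?:([^:]+):)?([0-9,]+)-([0-9,]+)$", query))[[1]]
  if (length(m) == 4) {
    contig <- m[2]
    a <- as.numeric(gsub(",", "", m[3]))
    b <- as.numeric(gsub(",", "", m[4]))
    if (contig == "") {
      if (length(records) > 1) {
        bescan_abort(
          "genome has several contigs; use 'contig:START-END'",
          "bescan_ambiguous_error"
        )
      }
      contig <- records[[1]]$contig_id
    }
    rec <- get_record(records, contig)
    if (a < 1 || b > rec$length || a > b) {
      bescan_abort(
        sprintf("range %s-%s outside contig '%s' (1-%d)", m[3], m[4],
                contig, rec$length),
        "bescan_bounds_error"
      )
    }
    return(target_region(contig, a - 1, b, query))
  }

  hits <- list()
  for (r in records) {
    for (f in r$features) {
      if (isTRUE(f$gene_name == query) || isTRUE(f$locus_tag == query) ||
          isTRUE(f$protein_id == query)) {
        hits[[length(hits) + 1L]] <- list(contig = r$contig_id, feature = f)
      }
    }
  }
  if (length(hits) == 0) {
    bescan_abort(sprintf("no feature matches query '%s'", query),
                 "bescan_not_found_error")
  }
  if (length(hits) > 1) {
    labels <- vapply(hits, function(h) {
      sprintf("%s:%d-%d", h$contig, min(h$feature$intervals[, 1]) + 1L,
              max(h$feature$intervals[, 2]))
    }, character(1))
    bescan_abort(
      sprintf("query '%s' matches %d features: %s", query, length(hits),
              paste(labels, collapse = "; ")),
      "bescan_ambiguous_error"
    )
  }
  f <- hits[[1]]$feature
  target_region(hits[[1]]$contig, min(f$intervals[, 1]),
                max(f$intervals[, 2]), query)
}
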