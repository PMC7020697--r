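#' Construct and validate a probe table
#'
#' A probe table is the array data model: one row per tiling probe with its
#' genomic interval (0-based, half-open) and one column of log2(MeDIP/Input)
#' values per sample. Rows are kept sorted by (chrom, start) and probe ids
#' must be unique.
#'
#' @param df data.frame with columns `probe_id`, `chrom`, `start`, `end`
#'   followed by one numeric column per sample.
#' @param sample_ids character vector naming the sample columns of `df`.
#'   Defaults to every column after the four coordinate columns.
#' @return A `probe_table` (a data.frame subclass) sorted by (chrom, start),
#'   with the sample ids recorded in `attr(x, "sample_ids")`.
#' @export
probe_table <- function(df, sample_ids = NULL) {
  req <- c("probe_id", "chrom", "start", "end")
  if (!all(req %in% names(df))) {
    stop("probe table needs columns: ", paste(req, collapse = ", "))
  }
  if (is.null(sample_ids)) {
    sample_ids <- setdiff(names(df), req)
  }
  if (length(sample_ids) < 1L) stop("probe table needs at least one sample column")
  missing_cols <- setdiff(sample_ids, names(df))
  if (length(missing_cols)) {
    stop("sample columns not found: ", paste(missing_cols, collapse = ", "))
  }
  dup <- duplicated(df$probe_id)
  if (any(dup)) {
    stop("duplicate probe_id: ", paste(unique(df$probe_id[dup]), collapse = ", "))
  }
  if (any(df$start >= df$end)) stop("probe intervals must satisfy start < end")
  for (s in sample_ids) df[[s]] <- as.numeric(df[[s]])
  df <- df[order(df$chrom, df$start, df$end), c(req, sample_ids), drop = FALSE]
  rownames(df) <- NULL
  structure(df, sample_ids = sample_ids, class = c("probe_table", "data.frame"))
}

#' Sample ids of a probe table
#' @param x a `probe_table`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) attr(x, "sample_ids")

#' Probe value matrix
#' @param x a `probe_table`.
#' @param samples optional subset of sample ids.
#' @return Numeric matrix, probes x samples.
#' @export
probe_values <- function(x, samples = NULL) {
  if (is.null(samples)) samples <- sample_ids(x)
  unknown <- setdiff(samples, sample_ids(x))
  if (length(unknown)) stop("unknown sample ids: ", paste(unknown, collapse = ", "))
  as.matrix(as.data.frame(x)[, samples, drop = FALSE])
}

#' Probe midpoints
#'
#' Midpoint of each probe interval, used as the probe's position for window
#' membership and gap rules.
#' @param x a `probe_table` or any data.frame with `start`/`end`.
#' @return Numeric vector of midpoints.
#' @export
probe_midpoints <- function(x) (x$start + x$end) / 2

#' Two-group sample design
#'
#' Assigns every array sample to one of exactly two analysis groups
#' (e.g. treatment vs control); each group needs at least two replicates.
#'
#' @param sample_id character vector of sample ids.
#' @param group character vector of group labels, parallel to `sample_id`.
#' @return A `group_design` data.frame with columns `sample_id`, `group`.
#' @export
group_design <- function(sample_id, group) {
  if (length(sample_id) != length(group)) stop("sample_id and group lengths differ")
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in design")
  tab <- table(group)
  if (length(tab) != 2L) stop("design must have exactly two groups, got: ",
                              paste(names(tab), collapse = ", "))
  if (any(tab < 2L)) {
    stop("each group needs >= 2 samples; group '",
         names(tab)[which.min(tab)], "' has ", min(tab))
  }
  structure(data.frame(sample_id = as.character(sample_id),
                       group = as.character(group),
                       stringsAsFactors = FALSE),
            class = c("group_design", "data.frame"))
}

#' Samples belonging to one design group
#' @param design a `group_design`.
#' @param group group label.
#' @return Character vector of sample ids.
#' @export
design_samples <- function(design, group) {
  if (!group %in% design$group) stop("unknown group: ", group)
  design$sample_id[design$group == group]
}

#' Read a probe table from TSV
#'
#' Reads tab-delimited probe-level array data. In `"log2"` format the sample
#' columns already hold log2(MeDIP/Input) ratios. In `"two_channel"` format
#' each sample contributes a pair of intensity columns named
#' `<sample>_MeDIP` and `<sample>_Input`, converted to log2(MeDIP/Input);
#' nonpositive intensities are rejected with the offending probe named.
#'
#' @param path TSV file with header; columns `probe_id`, `chrom`, `start`,
#'   `end`, then sample columns.
#' @param format `"log2"` (default) or `"two_channel"`.
#' @return A [probe_table()].
#' @export
read_probe_table <- function(path, format = c("log2", "two_channel")) {
  format <- match.arg(format)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("probe_id", "chrom", "start", "end")
  if (!all(req %in% names(df))) {
    stop("probe table file needs columns: ", paste(req, collapse = ", "))
  }
  value_cols <- setdiff(names(df), req)
  if (format == "two_channel") {
    medip_cols <- grep("_MeDIP$", value_cols, value = TRUE)
    samples <- sub("_MeDIP$", "", medip_cols)
    if (length(samples) == 0L) stop("no <sample>_MeDIP columns found")
    input_cols <- paste0(samples, "_Input")
    missing_in <- setdiff(input_cols, value_cols)
    if (length(missing_in)) {
      stop("missing Input columns: ", paste(missing_in, collapse = ", "))
    }
    out <- df[req]
    for (i in seq_along(samples)) {
      medip <- df[[medip_cols[i]]]
      input <- df[[input_cols[i]]]
      bad <- which(medip <= 0 | input <= 0)
      if (length(bad)) {
        stop("nonpositive intensity for sample '", samples[i],
             "' at probe(s): ", paste(df$probe_id[utils::head(bad, 5L)], collapse = ", "))
      }
      out[[samples[i]]] <- log2(medip / input)
    }
    probe_table(out, samples)
  } else {
    probe_table(df, value_cols)
  }
}

#' Write a probe table to TSV
#' @param x a `probe_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write peaks or DEPs as BED6
#'
#' Intervals are written 0-based half-open; the score column carries the
#' peak score (median -log10 p of member probes) clamped to \[0, 1000\] and
#' strand is ".". An empty record set produces an empty file with no header.
#'
#' @param records data.frame with `chrom`, `start`, `end`; optional `name`
#'   and `score` columns (defaults: `peak_<i>`, 0).
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  if (nrow(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(records)) records$name else
    paste0("peak_", seq_len(nrow(records)))
  score <- if ("score" %in% names(records)) records$score else 0
  score <- pmin(pmax(score, 0), 1000)
  bed <- data.frame(chrom = records$chrom,
                    start = format(records$start, scientific = FALSE, trim = TRUE),
                    end = format(records$end, scientific = FALSE, trim = TRUE),
                    name = name, score = score, strand = ".",
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#' @param path BED file written by [write_bed()] (or any >= 3 column BED).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (missing columns filled with defaults); empty file gives a
#'   zero-row frame.
#' @export
read_bed <- function(path) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(ncol(df))]
  if (!"name" %in% names(df)) df$name <- paste0("peak_", seq_len(nrow(df)))
  if (!"score" %in% names(df)) df$score <- 0
  if (!"strand" %in% names(df)) df$strand <- "."
  df[cols]
}

#' Read promoter sequences with their annotation
#'
#' Joins a promoter FASTA (ids = gene ids) to a BED-like annotation table
#' (`gene_id`, `chrom`, `tss`, `strand`, and the promoter window columns
#' `win_start`, `win_end` in absolute 0-based half-open coordinates).
#' Sequences are upper-cased and must be over A/C/G/T/N.
#'
#' @param path FASTA file of promoter sequences.
#' @param annotation_path TSV with header as described above.
#' @return data.frame of promoter records with a `sequence` column.
#' @export
read_fasta_promoters <- function(path, annotation_path) {
  # read as plain strings first so invalid letters are rejected, not dropped
  seqs <- Biostrings::readBStringSet(path)
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "tss", "strand", "win_start", "win_end")
  if (!all(req %in% names(ann))) {
    stop("promoter annotation needs columns: ", paste(req, collapse = ", "))
  }
  ids <- names(seqs)
  missing_seq <- setdiff(ann$gene_id, ids)
  if (length(missing_seq)) {
    stop("no FASTA entry for gene_id: ", paste(missing_seq, collapse = ", "))
  }
  extra <- setdiff(ids, ann$gene_id)
  if (length(extra)) {
    stop("FASTA id without annotation row: ", paste(extra, collapse = ", "))
  }
  chars <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) {
    stop("non-ACGTN character in sequence(s): ", paste(ids[bad], collapse = ", "))
  }
  ann$sequence <- chars[match(ann$gene_id, names(seqs))]
  widths <- ann$win_end - ann$win_start
  mismatch <- nchar(ann$sequence) != widths
  if (any(mismatch)) {
    stop("sequence length != window length for: ",
         paste(ann$gene_id[mismatch], collapse = ", "))
  }
  ann
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `set_id`, description,
#' then member gene ids.
#'
#' @param path GMT file.
#' @param universe optional character vector of gene ids to restrict the
#'   sets to (membership outside the universe is dropped; sets left empty
#'   after restriction are removed).
#' @return A `gene_set_collection`: list with `sets` (named list of
#'   character vectors), `descriptions` (named character) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short)) stop("GMT line with fewer than 3 fields at line ", which(short)[1L])
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate set id in GMT: ", ids[duplicated(ids)][1L])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  desc <- vapply(parts, `[[`, "", 2L)
  names(desc) <- ids
  gene_set_collection(sets, desc, universe)
}

#' Build a gene-set collection
#' @param sets named list of character vectors of member gene ids.
#' @param descriptions optional named character vector of descriptions.
#' @param universe optional gene universe; defaults to the union of members.
#'   When given, members are restricted to it and emptied sets dropped.
#' @return A `gene_set_collection` list.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) stop("sets must be named")
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- sort(unique(as.character(universe)))
    sets <- lapply(sets, intersect, y = universe)
    keep <- vapply(sets, length, 1L) > 0L
    sets <- sets[keep]
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  } else {
    descriptions <- descriptions[names(sets)]
  }
  structure(list(sets = sets, descriptions = descriptions, universe = universe),
            class = "gene_set_collection")
}

#' Read bisulfite clone matrices from TSV
#'
#' Long-format TSV with header `animal_id`, `group`, `amplicon_id`,
#' `clone_id`, then one column per CpG site (`cpg_1`, `cpg_2`, ...). Calls
#' are 0 (unmethylated), 1 (methylated) or NA (missing).
#'
#' @param path TSV file.
#' @return List of `bisulfite_clone_matrix` objects (one per animal x
#'   amplicon), each a list with `animal_id`, `group`, `amplicon_id` and a
#'   clones x sites integer matrix `calls`.
#' @export
read_clone_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "group", "amplicon_id", "clone_id")
  if (!all(req %in% names(df))) {
    stop("clone table needs columns: ", paste(req, collapse = ", "))
  }
  site_cols <- setdiff(names(df), req)
  if (length(site_cols) == 0L) stop("clone table has no CpG site columns")
  vals <- as.matrix(df[site_cols])
  ok <- is.na(vals) | vals %in% c(0, 1)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop("clone call outside {0,1,NA} at row ", bad[1L],
         ", site ", site_cols[bad[2L]])
  }
  key <- interaction(df$animal_id, df$amplicon_id, drop = TRUE)
  lapply(split(seq_len(nrow(df)), key), function(idx) {
    grp <- unique(df$group[idx])
    if (length(grp) != 1L) stop("inconsistent group for animal ", df$animal_id[idx[1L]])
    calls <- matrix(as.integer(vals[idx, , drop = FALSE]),
                    nrow = length(idx),
                    dimnames = list(df$clone_id[idx], site_cols))
    bisulfite_clone_matrix(df$animal_id[idx[1L]], grp,
                           df$amplicon_id[idx[1L]], calls)
  })
}

#' Construct a bisulfite clone matrix
#' @param animal_id animal identifier.
#' @param group group label.
#' @param amplicon_id amplicon (gene region) identifier.
#' @param calls clones x CpG-sites matrix with entries 0/1/NA.
#' @return A `bisulfite_clone_matrix` list.
#' @export
bisulfite_clone_matrix <- function(animal_id, group, amplicon_id, calls) {
  calls <- as.matrix(calls)
  if (nrow(calls) < 1L) stop("clone matrix needs >= 1 clone")
  ok <- is.na(calls) | calls %in% c(0L, 1L)
  if (!all(ok)) stop("clone calls must be 0, 1 or NA")
  structure(list(animal_id = as.character(animal_id), group = as.character(group),
                 amplicon_id = as.character(amplicon_id),
                 calls = matrix(as.integer(calls), nrow = nrow(calls),
                                dimnames = dimnames(calls))),
            class = "bisulfite_clone_matrix")
}

#' Read a phenotype table
#'
#' TSV with header: `animal_id`, `group`, `body_weight`, glucose columns
#' `glucose_<minute>` (e.g. `glucose_0`, `glucose_15`, ..., `glucose_120`),
#' `fasting_insulin`, and optional Ct columns `ct_<gene>`.
#'
#' @param path TSV file.
#' @param groups allowed group labels (default CON, HF, HF-inulin).
#' @return data.frame with an attribute `glucose_times` giving the sampled
#'   minutes in increasing order.
#' @export
read_phenotypes <- function(path, groups = c("CON", "HF", "HF-inulin")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("animal_id", "group", "body_weight", "fasting_insulin")
  if (!all(req %in% names(df))) {
    stop("phenotype table needs columns: ", paste(req, collapse = ", "))
  }
  unknown <- setdiff(unique(df$group), groups)
  if (length(unknown)) stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  gcols <- grep("^glucose_", names(df), value = TRUE)
  if (length(gcols) < 2L) stop("need >= 2 glucose_<minute> columns")
  times <- as.numeric(sub("^glucose_", "", gcols))
  if (anyNA(times)) stop("malformed glucose column name")
  ord <- order(times)
  times <- times[ord]
  if (times[1L] != 0) stop("glucose series must start at minute 0")
  if (any(diff(times) <= 0)) stop("glucose times must be strictly increasing")
  meas <- c("body_weight", "fasting_insulin", gcols)
  if (any(as.matrix(df[meas]) < 0, na.rm = TRUE)) stop("measurements must be >= 0")
  structure(df, glucose_times = times,
            glucose_cols = gcols[ord], class = c("phenotype_table", "data.frame"))
}
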