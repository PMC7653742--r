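# Per-gene mean exonic depth from depth tracks and gene annotations.
# Coordinates follow GRanges conventions (1-based closed); rtracklayer
# performs the GFF3 / BED12 / bedGraph conversions at the file boundary.

#' Read a gene annotation (GFF3 or BED12)
#'
#' Parses gene models into per-gene exon sets. GFF3 files are expected to
#' carry gene/mRNA/exon features linked by `Parent` attributes (exons with
#' a gene `Parent` directly are also accepted); BED12 blocks are taken as
#' exons and the `name` field as the gene id. Overlapping exon records of
#' a gene are merged to their union, so depth is averaged over each exonic
#' base once.
#'
#' @param path path to a `.gff3`/`.gff` or `.bed` file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param cds_only for GFF3: use CDS features instead of exons when
#'   present, restricting depth averaging to coding sequence.
#' @return A `GRangesList`, one element per gene (named by gene id), of
#'   merged, sorted exon ranges.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed"),
                            cds_only = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io(sprintf("annotation file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(gr$name) || anyNA(gr$name)) {
      abort_validation("BED12 records must carry a name (gene id)")
    }
    if (!is.null(gr$blocks)) {
      # blocks are feature-relative; lift to genomic coordinates
      shifted <- IRanges::shift(gr$blocks, GenomicRanges::start(gr) - 1L)
      ex <- unlist(shifted, use.names = FALSE)
      gene_id <- rep(gr$name, lengths(shifted))
      scaf <- rep(as.character(GenomicRanges::seqnames(gr)), lengths(shifted))
      strnd <- rep(as.character(GenomicRanges::strand(gr)), lengths(shifted))
      exon_gr <- GenomicRanges::GRanges(scaf, ex, strand = strnd)
    } else {
      exon_gr <- GenomicRanges::granges(gr)
      gene_id <- gr$name
    }
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    feat <- if (cds_only && any(gr$type == "CDS")) "CDS" else "exon"
    ex <- gr[gr$type == feat]
    if (length(ex) == 0L) abort_validation("no exon/CDS features in annotation")
    parent <- as.character(S4Vectors::unstrsplit(ex$Parent, ","))
    if (anyNA(parent) || any(parent == "")) {
      abort_validation("exon features must carry a Parent attribute")
    }
    # resolve transcript parents to gene ids where a transcript layer exists
    tx <- gr[gr$type %in% c("mRNA", "transcript")]
    gene_of_tx <- setNames(as.character(S4Vectors::unstrsplit(tx$Parent, ",")),
                           tx$ID)
    gene_id <- ifelse(parent %in% names(gene_of_tx),
                      gene_of_tx[parent], parent)
    exon_gr <- GenomicRanges::granges(ex)
    gene_id <- unname(gene_id)
  }
  grl <- S4Vectors::split(exon_gr, factor(gene_id, levels = unique(gene_id)))
  grl <- GenomicRanges::reduce(grl)  # merge overlapping records, sort
  if (any(sum(IRanges::width(grl)) == 0L)) {
    abort_validation("gene with zero exonic length in annotation")
  }
  grl
}

#' Depth tracks
#'
#' A depth track stores one individual's per-base depth as one run-length
#' encoded vector per scaffold. `read_depth_track()` builds one from a
#' bedGraph file (positions not covered by any interval count as depth 0);
#' `depth_track()` builds one from a named list of [S4Vectors::Rle]
#' vectors.
#'
#' @param path path to a bedGraph file.
#' @param individual_id id for the individual; defaults to the file name
#'   without extension.
#' @return An object of class `pav_depth_track`.
#' @export
read_depth_track <- function(path, individual_id = NULL) {
  if (!file.exists(path)) abort_io(sprintf("depth track not found: %s", path))
  individual_id <- individual_id %||%
    sub("\\.(bedgraph|bdg|bg)$", "", basename(path), ignore.case = TRUE)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0)) abort_validation("negative depth in bedGraph")
  rles <- lapply(S4Vectors::split(gr, GenomicRanges::seqnames(gr), drop = TRUE),
                 function(x) {
    x <- GenomicRanges::sort(x)
    s <- GenomicRanges::start(x); e <- GenomicRanges::end(x)
    if (length(x) > 1L && any(s[-1L] <= e[-length(e)])) {
      abort_validation("overlapping intervals in bedGraph")
    }
    # fill gaps (including a leading gap) with depth 0
    gap_before <- s - c(0L, e[-length(e)]) - 1L
    vals <- as.vector(rbind(0, x$score))
    lens <- as.vector(rbind(gap_before, e - s + 1L))
    keep <- lens > 0L
    S4Vectors::Rle(vals[keep], lens[keep])
  })
  depth_track(rles, individual_id)
}

#' @rdname read_depth_track
#' @param depth named list (by scaffold) of `Rle` per-base depth vectors.
#' @export
depth_track <- function(depth, individual_id) {
  if (!is.list(depth) || is.null(names(depth)) ||
      !all(vapply(depth, function(x) methods::is(x, "Rle"), logical(1)))) {
    abort_validation("`depth` must be a named list of Rle vectors")
  }
  if (any(vapply(depth, function(x) any(S4Vectors::runValue(x) < 0), logical(1)))) {
    abort_validation("depths must be >= 0")
  }
  structure(list(individual_id = individual_id, depth = depth),
            class = "pav_depth_track")
}

#' @export
print.pav_depth_track <- function(x, ...) {
  cat(sprintf("pav_depth_track '%s': %d scaffolds, %.0f bases\n",
              x$individual_id, length(x$depth),
              sum(vapply(x$depth, length, numeric(1)))))
  invisible(x)
}

# Sum of depth over [start, end] (1-based closed) on one scaffold Rle,
# counting positions beyond the track as depth 0.
rle_interval_sums <- function(rle, starts, ends) {
  n <- length(rle)
  need <- max(0L, max(ends) - n)
  if (need > 0L) rle <- c(rle, S4Vectors::Rle(0, need))
  v <- IRanges::Views(rle, start = starts, end = ends)
  IRanges::viewSums(v)
}

#' Mean exonic depth of one gene in one individual
#'
#' Averages per-base depth over the gene's exonic bases:
#' sum(depth over exon bases) / total exonic length. Strand is ignored;
#' scaffolds (or positions) absent from the track count as depth 0.
#'
#' @param track a `pav_depth_track`.
#' @param gene a `GRanges` of one gene's exons (one element of the
#'   `GRangesList` returned by [read_annotation()]).
#' @return Mean depth (X), a single number.
#' @export
gene_mean_depth <- function(track, gene) {
  stopifnot(inherits(track, "pav_depth_track"))
  if (length(gene) == 0L) abort_validation("gene has no exons")
  scaf <- as.character(GenomicRanges::seqnames(gene))
  total_bases <- sum(IRanges::width(gene))
  if (total_bases == 0L) abort_validation("gene has zero exonic length")
  total <- 0
  for (sc in unique(scaf)) {
    idx <- scaf == sc
    rle <- track$depth[[sc]]
    if (is.null(rle)) next  # unmapped scaffold: depth 0
    total <- total + sum(rle_interval_sums(rle,
                                           GenomicRanges::start(gene)[idx],
                                           GenomicRanges::end(gene)[idx]))
  }
  total / total_bases
}

#' Build the individuals x genes coverage matrix
#'
#' Computes mean exonic depth for every (gene, individual) pair. The raw
#' layer is in depth units (X); the normalized layer (unitless, 1.0 = one
#' allele) is added later by [normalize_matrix()].
#'
#' @param tracks list of `pav_depth_track` objects (one per individual).
#' @param annotation `GRangesList` of per-gene exons ([read_annotation()]).
#' @return An object of class `pav_coverage_matrix` with elements `raw`
#'   (genes x individuals matrix), `normalized` (NULL until calibration),
#'   `genes`, `individuals`.
#' @export
build_matrix <- function(tracks, annotation) {
  if (inherits(tracks, "pav_depth_track")) tracks <- list(tracks)
  if (length(tracks) < 1L) abort_validation("need at least one depth track")
  if (length(annotation) < 1L) abort_validation("need at least one gene")
  ids <- vapply(tracks, function(t) t$individual_id, character(1))
  if (anyDuplicated(ids)) abort_validation("duplicate individual ids in tracks")
  gene_ids <- names(annotation)
  if (is.null(gene_ids) || anyDuplicated(gene_ids)) {
    abort_validation("annotation must have unique gene ids as names")
  }

  ex <- unlist(annotation, use.names = FALSE)
  gene_of_exon <- rep(seq_along(annotation), lengths(annotation))
  scaf <- as.character(GenomicRanges::seqnames(ex))
  starts <- GenomicRanges::start(ex); ends <- GenomicRanges::end(ex)
  gene_len <- as.numeric(sum(IRanges::width(annotation)))
  if (any(gene_len == 0)) abort_validation("gene with zero exonic length")

  raw <- matrix(0, nrow = length(annotation), ncol = length(tracks),
                dimnames = list(gene_ids, ids))
  by_scaf <- split(seq_along(ex), scaf)
  for (ti in seq_along(tracks)) {
    tr <- tracks[[ti]]
    sums <- numeric(length(annotation))
    for (sc in names(by_scaf)) {
      rle <- tr$depth[[sc]]
      if (is.null(rle)) next
      idx <- by_scaf[[sc]]
      s <- rle_interval_sums(rle, starts[idx], ends[idx])
      agg <- rowsum(as.numeric(s), gene_of_exon[idx])
      sums[as.integer(rownames(agg))] <- sums[as.integer(rownames(agg))] + agg[, 1L]
    }
    raw[, ti] <- sums / gene_len
  }
  new_coverage_matrix(raw)
}

new_coverage_matrix <- function(raw, normalized = NULL, meta = list()) {
  structure(
    list(raw = raw, normalized = normalized,
         genes = rownames(raw), individuals = colnames(raw), meta = meta),
    class = "pav_coverage_matrix"
  )
}

#' @export
print.pav_coverage_matrix <- function(x, ...) {
  cat(sprintf("pav_coverage_matrix: %d genes x %d individuals (%s)\n",
              nrow(x$raw), ncol(x$raw),
              if (is.null(x$normalized)) "raw" else "raw + normalized"))
  invisible(x)
}

#' Write a coverage matrix layer as TSV (genes as rows)
#'
#' @param x a `pav_coverage_matrix`.
#' @param path output path.
#' @param layer `"raw"` or `"normalized"`.
#' @export
write_coverage_matrix <- function(x, path, layer = c("raw", "normalized")) {
  layer <- match.arg(layer)
  m <- x[[layer]]
  if (is.null(m)) abort_validation(sprintf("layer '%s' not present", layer))
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
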