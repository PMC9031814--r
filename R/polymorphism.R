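#' Per-gene polymorphism table from variant records
#'
#' Counts, for each gene, the number of segregating sites K (distinct
#' positions with 0 < allele count < total chromosomes), the number of
#' singleton sites (an allele — alternate or reference — observed on exactly
#' one chromosome), and de-novo mutations, over the gene's footprint. The
#' footprint of a gene is the union of its annotated intervals (typically
#' the CDS exons), and its length L is the union width; q = K / L. A site
#' overlapped by two genes is counted once per gene.
#'
#' @param variants Variant data frame as returned by [read_variants()].
#' @param genes Feature intervals (`chrom start end feature gene_id`,
#'   0-based half-open); rows with empty `gene_id` are ignored.
#' @param denovo Optional variant data frame of de-novo mutation positions.
#' @param x_chroms Chromosome names treated as the X chromosome.
#' @return `data.frame(gene_id, K, singletons, de_novo, L, q, chrom, is_X)`.
#' @export
tabulate_gene_variation <- function(variants, genes, denovo = NULL,
                                    x_chroms = c("X", "chrX")) {
  genes <- genes[genes$gene_id != "", , drop = FALSE]
  if (nrow(genes) == 0L)
    stop("tabulate_gene_variation: no gene-labelled intervals")
  ids <- unique(genes$gene_id)
  seg <- variants$alt_allele_count > 0 &
    variants$alt_allele_count < variants$total_chromosomes
  single <- variants$alt_allele_count == 1L |
    variants$alt_allele_count == variants$total_chromosomes - 1L
  out <- lapply(ids, function(gid) {
    iv <- genes[genes$gene_id == gid, , drop = FALSE]
    chrom <- iv$chrom[1L]
    ir <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L, end = iv$end))
    L <- sum(IRanges::width(ir))
    inside <- function(v) {
      v$chrom == chrom &
        IRanges::overlapsAny(IRanges::IRanges(start = v$pos, width = 1L), ir)
    }
    in_gene <- inside(variants)
    k <- length(unique(variants$pos[in_gene & seg]))
    s <- length(unique(variants$pos[in_gene & seg & single]))
    dn <- if (is.null(denovo)) 0L else sum(inside(denovo))
    data.frame(gene_id = gid, K = k, singletons = s, de_novo = dn,
               L = L, q = k / L, chrom = chrom,
               is_X = chrom %in% x_chroms, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  drop <- out$L == 0L
  if (any(drop)) {
    warning("tabulate_gene_variation: dropping ", sum(drop), " gene(s) with L = 0")
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Nucleotide diversity in fixed 1000-bp windows
#'
#' Per window, pi is the sum of unbiased per-site heterozygosities
#' `2 * p * (1 - p) * n / (n - 1)` (p the alternate-allele frequency, n the
#' number of chromosomes) divided by the nominal window width, so that
#' `sum(pi) * width` over windows conserves the per-site total.
#'
#' @param variants Variant data frame ([read_variants()] output), one
#'   chromosome.
#' @param chrom_length Chromosome length in bp.
#' @param width Window width in bp (default 1000).
#' @return `data.frame(chrom, start, pi)` with `start` 0-based; windows are
#'   `[start, start + width)`, the last possibly truncated at
#'   `chrom_length`.
#' @export
window_pi <- function(variants, chrom_length, width = 1000L) {
  stopifnot(chrom_length >= 1L)
  chrom <- if (nrow(variants)) variants$chrom[1L] else NA_character_
  starts <- seq.int(0L, chrom_length - 1L, by = width)
  pi <- numeric(length(starts))
  if (nrow(variants)) {
    bad_n <- variants$total_chromosomes < 2L
    if (any(bad_n)) {
      warning("window_pi: ", sum(bad_n), " site(s) with n < 2 skipped")
      variants <- variants[!bad_n, , drop = FALSE]
    }
    p <- variants$alt_allele_count / variants$total_chromosomes
    n <- variants$total_chromosomes
    het <- 2 * p * (1 - p) * n / (n - 1)
    idx <- (variants$pos - 1L) %/% width + 1L
    ok <- idx >= 1L & idx <= length(starts)
    agg <- tapply(het[ok], idx[ok], sum)
    pi[as.integer(names(agg))] <- agg / width
  }
  data.frame(chrom = chrom, start = starts, pi = pi, stringsAsFactors = FALSE)
}

#' Assign a feature label to each diversity window
#'
#' A window farther than `intergenic_dist` bp from every annotated gene
#' boundary (the outermost coordinates of the gene's intervals, i.e. the
#' start/stop-codon ends of its footprint) is `intergenic`. Otherwise the
#' window takes the feature class covering the majority of its overlapped
#' bases, with precedence exon > utr5 > utr3 > intron on exact ties. A
#' window near a gene but overlapping no annotated feature gets `NA` (the
#' closed label set has no name for it, and it is excluded from model
#' fitting).
#'
#' @param windows Window data frame from [window_pi()] (needs `chrom`,
#'   `start`), with an implicit width.
#' @param features Feature interval data frame.
#' @param width Window width in bp.
#' @param intergenic_dist Distance rule in bp (default 100000).
#' @return `windows` with a `feature` column added.
#' @export
assign_window_feature <- function(windows, features, width = 1000L,
                                  intergenic_dist = 100000L) {
  cls <- c("exon", "utr5", "utr3", "intron")
  feat <- character(nrow(windows))
  gene_rows <- features[features$gene_id != "", , drop = FALSE]
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    fs <- features[features$chrom == ch & features$feature %in% cls, , drop = FALSE]
    gb <- gene_rows[gene_rows$chrom == ch, , drop = FALSE]
    bounds <- if (nrow(gb)) {
      do.call(rbind, lapply(split(gb, gb$gene_id), function(g)
        c(min(g$start), max(g$end))))
    } else matrix(numeric(0), ncol = 2L)
    fr <- IRanges::IRanges(start = fs$start + 1L, end = fs$end)
    for (j in wi) {
      ws <- windows$start[j]
      we <- ws + width
      # distance from window [ws, we) to each gene's [start, end) footprint
      dmin <- if (nrow(bounds)) {
        min(pmax(0, pmax(bounds[, 1L] - we, ws - bounds[, 2L])))
      } else Inf
      if (dmin > intergenic_dist) {
        feat[j] <- "intergenic"
        next
      }
      wr <- IRanges::IRanges(start = ws + 1L, end = we)
      ov <- IRanges::pintersect(IRanges::findOverlapPairs(wr, fr))
      if (length(ov) == 0L) {
        feat[j] <- NA_character_
        next
      }
      fhit <- fs$feature[S4Vectors::subjectHits(IRanges::findOverlaps(wr, fr))]
      cover <- tapply(IRanges::width(ov), fhit, sum)
      cover <- cover[cls[cls %in% names(cover)]]  # precedence order
      feat[j] <- names(cover)[which.max(cover)]
    }
  }
  windows$feature <- feat
  windows
}

#' Interpolated genetic-map position (cumulative cM)
#'
#' Linear interpolation within the map; linear extrapolation beyond its
#' ends using the slope of the terminal segment.
#'
#' @param map `data.frame(position, cM)`, positions strictly increasing.
#' @param pos Physical position(s), bp.
#' @return Cumulative cM at `pos`.
#' @export
interpolate_cM <- function(map, pos) {
  if (nrow(map) == 0L) stop("interpolate_cM: empty map")
  if (nrow(map) == 1L) return(rep(map$cM[1L], length(pos)))
  out <- approx(map$position, map$cM, xout = pos, rule = 1L)$y
  lo <- pos < map$position[1L]
  hi <- pos > map$position[nrow(map)]
  if (any(lo)) {
    s <- (map$cM[2L] - map$cM[1L]) / (map$position[2L] - map$position[1L])
    out[lo] <- map$cM[1L] + s * (pos[lo] - map$position[1L])
  }
  if (any(hi)) {
    nm <- nrow(map)
    s <- (map$cM[nm] - map$cM[nm - 1L]) / (map$position[nm] - map$position[nm - 1L])
    out[hi] <- map$cM[nm] + s * (pos[hi] - map$position[nm])
  }
  out
}

#' Recombination fraction between two positions via the genetic map
#'
#' The cM distance between the positions is obtained by linear
#' interpolation of the cumulative map and converted to a recombination
#' fraction with the Haldane map function
#' `R = 0.5 * (1 - exp(-2 d / 100))`, so `0 <= R < 0.5`.
#'
#' @param map Genetic map (`position`, `cM`).
#' @param pos_a,pos_b Physical positions in bp (either may be vectors).
#' @return Recombination fraction(s).
#' @export
window_recombination <- function(map, pos_a, pos_b) {
  d <- abs(interpolate_cM(map, pos_a) - interpolate_cM(map, pos_b))
  haldane_fraction(d)
}

#' Haldane map function: cM distance to recombination fraction
#' @param d_cM Genetic distance in centimorgans.
#' @return `0.5 * (1 - exp(-2 * d_cM / 100))`.
#' @export
haldane_fraction <- function(d_cM) {
  0.5 * (1 - exp(-2 * d_cM / 100))
}
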