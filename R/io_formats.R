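#' @importFrom stats approx cor median optim pnbinom dnbinom qnorm pnorm pt
#'   rpois rnbinom rbinom rlnorm rnorm runif sd var prcomp aov p.adjust
#'   logLik coef qchisq uniroot setNames quantile complete.cases
#' @importFrom utils read.table write.table head tail
NULL

.feature_levels <- c("exon", "utr5", "utr3", "intron", "intergenic")

#' Construct a gene tree object
#'
#' A `gene_tree` carries the per-branch substitution estimates of one gene's
#' inferred phylogeny together with the alignment length used to infer it.
#' Branch lengths are in expected substitutions per site.
#'
#' @param gene_id Gene identifier.
#' @param branch_lengths Numeric vector of non-negative branch lengths
#'   (substitutions/site), one per branch of the tree.
#' @param taxon_labels Character vector of tip labels.
#' @param alignment_length Positive integer, number of alignment sites.
#' @return An object of class `gene_tree`.
#' @export
gene_tree <- function(gene_id, branch_lengths, taxon_labels, alignment_length) {
  branch_lengths <- as.numeric(branch_lengths)
  alignment_length <- as.integer(alignment_length)
  if (length(branch_lengths) < 1L)
    stop("gene_tree: at least one branch is required (gene ", gene_id, ")")
  if (any(branch_lengths < 0))
    stop("gene_tree: negative branch length (gene ", gene_id, ")")
  if (is.na(alignment_length) || alignment_length < 1L)
    stop("gene_tree: alignment_length must be >= 1 (gene ", gene_id, ")")
  structure(
    list(gene_id = as.character(gene_id),
         branch_lengths = branch_lengths,
         taxon_labels = as.character(taxon_labels),
         alignment_length = alignment_length),
    class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("<gene_tree> %s: %d branches, %d taxa, %d sites, total length %.4g\n",
              x$gene_id, length(x$branch_lengths), length(x$taxon_labels),
              x$alignment_length, sum(x$branch_lengths)))
  invisible(x)
}

#' Read gene trees from newick files
#'
#' Each file holds one newick tree; the gene id is the file name without its
#' extension. Alignment lengths are supplied through a sidecar lookup keyed by
#' gene id. All branches of the tree are retained, including zero-length
#' internal branches; no root edge is synthesized (ML gene trees are
#' effectively unrooted, and downstream summaries consume the branch
#' multiset).
#'
#' @param paths Character vector of newick file paths.
#' @param alignment_lengths Named numeric vector or data frame with columns
#'   `gene_id` and `alignment_length`.
#' @return A named list of [gene_tree()] objects.
#' @export
read_gene_trees <- function(paths, alignment_lengths) {
  if (is.data.frame(alignment_lengths)) {
    alignment_lengths <- setNames(alignment_lengths$alignment_length,
                                  alignment_lengths$gene_id)
  }
  trees <- lapply(paths, function(p) {
    gid <- sub("\\.[^.]*$", "", basename(p))
    phy <- tryCatch(ape::read.tree(p),
                    error = function(e) NULL)
    if (is.null(phy))
      stop("read_gene_trees: unparsable newick in ", p)
    if (!gid %in% names(alignment_lengths))
      stop("read_gene_trees: no alignment length for gene ", gid)
    gene_tree(gid, phy$edge.length, phy$tip.label, alignment_lengths[[gid]])
  })
  names(trees) <- vapply(trees, `[[`, "", "gene_id")
  trees
}

#' Read biallelic SNP records from a VCF file
#'
#' Returns one row per alternate allele with its allele count (AC) and the
#' total number of chromosomes sampled (AN). Multi-allelic sites are split
#' into one record per alternate allele. Counts are taken from the INFO
#' AC/AN fields when present, otherwise derived from the genotype columns.
#' Indels and other non-SNP alleles are skipped; the number skipped is
#' attached as attribute `n_skipped` and reported via a warning.
#'
#' @param vcf_path Path to a VCF (v4.x) file.
#' @param region Optional `list(chrom =, start =, end =)` restricting output
#'   to records with `chrom` equal and 1-based position in `[start, end]`.
#' @param is_de_novo Logical flag copied onto every record (used when the
#'   file is a de-novo mutation table).
#' @return `data.frame(chrom, pos, alt_allele_count, total_chromosomes,
#'   is_de_novo)` with `pos` 1-based per the VCF convention.
#' @export
read_variants <- function(vcf_path, region = NULL, is_de_novo = FALSE) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(.empty_variants())
  ac <- suppressWarnings(vcfR::extract.info(vcf, "AC"))
  an <- suppressWarnings(vcfR::extract.info(vcf, "AN", as.numeric = TRUE))
  gt <- if (ncol(vcf@gt) > 1L) vcfR::extract.gt(vcf, element = "GT") else NULL
  n_skipped <- 0L
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix$REF[i]
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (is.na(ref) || nchar(ref) != 1L) {
      n_skipped <- n_skipped + 1L
      next
    }
    no_alt <- is.na(alts) | alts == "."   # monomorphic record: nothing to emit
    snp <- !no_alt & nchar(alts) == 1L & alts != "*"
    n_skipped <- n_skipped + sum(!snp & !no_alt)
    if (!any(snp)) next
    acs <- ans <- NULL
    if (!is.null(ac) && !is.na(ac[i]) && !is.na(an[i])) {
      acs <- as.numeric(strsplit(ac[i], ",", fixed = TRUE)[[1]])
      ans <- rep(an[i], length(alts))
    } else if (!is.null(gt)) {
      al <- unlist(strsplit(gt[i, ], "[/|]"))
      al <- al[!is.na(al) & al != "."]
      ans <- rep(length(al), length(alts))
      acs <- vapply(seq_along(alts), function(j) sum(al == as.character(j)), 0)
    } else {
      stop("read_variants: record without AC/AN and without genotypes at ",
           fix$CHROM[i], ":", fix$POS[i])
    }
    keep <- which(snp)
    if (length(keep) == 0L) next
    rows[[i]] <- data.frame(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      alt_allele_count = as.integer(acs[keep]),
      total_chromosomes = as.integer(ans[keep]),
      is_de_novo = is_de_novo, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- .empty_variants()
  bad <- out$alt_allele_count < 0 | out$alt_allele_count > out$total_chromosomes
  if (any(bad)) {
    warning("read_variants: ", sum(bad), " malformed records skipped")
    n_skipped <- n_skipped + sum(bad)
    out <- out[!bad, , drop = FALSE]
  }
  if (!is.null(region)) {
    out <- out[out$chrom == region$chrom &
               out$pos >= region$start & out$pos <= region$end, , drop = FALSE]
  }
  rownames(out) <- NULL
  if (n_skipped > 0L)
    warning("read_variants: skipped ", n_skipped, " non-SNP/malformed allele(s)")
  attr(out, "n_skipped") <- n_skipped
  out
}

.empty_variants <- function() {
  data.frame(chrom = character(), pos = integer(),
             alt_allele_count = integer(), total_chromosomes = integer(),
             is_de_novo = logical())
}

#' Read a feature track and a genetic map
#'
#' The feature track is BED-like: whitespace-separated columns
#' `chrom start end feature gene_id`, 0-based half-open coordinates, with
#' `feature` drawn from exon / utr5 / utr3 / intron / intergenic. The genetic
#' map is a 2-column table `position cumulative_cM` (or 3 columns with a
#' leading `chrom`). Overlapping feature intervals are preserved as given;
#' overlap resolution is the business of [assign_window_feature()].
#'
#' @param feature_path Path to the feature track.
#' @param map_path Path to the genetic map table.
#' @return `list(features = data.frame, map = data.frame(position, cM))`,
#'   features sorted by (chrom, start).
#' @export
read_tracks <- function(feature_path, map_path) {
  features <- read.table(feature_path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "feature", "gene_id"),
                         fill = TRUE)
  features$gene_id[is.na(features$gene_id)] <- ""
  if (any(features$start >= features$end))
    stop("read_tracks: interval with start >= end in ", feature_path)
  if (!all(features$feature %in% .feature_levels))
    stop("read_tracks: unknown feature label(s): ",
         paste(setdiff(unique(features$feature), .feature_levels), collapse = ", "))
  features <- features[order(features$chrom, features$start), ]
  rownames(features) <- NULL

  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) == 3L) map <- map[, 2:3]
  names(map) <- c("position", "cM")
  if (is.unsorted(map$position, strictly = TRUE))
    stop("read_tracks: genetic map positions must be strictly increasing")
  if (is.unsorted(map$cM))
    stop("read_tracks: genetic map cM must be non-decreasing")
  list(features = features, map = map)
}

#' Write a data frame as a TSV with header
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
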