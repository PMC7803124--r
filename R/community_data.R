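#' @keywords internal
"_PACKAGE"

# Canonical taxonomic ranks, coarsest to finest.
TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Construct a community table
#'
#' A community table holds a samples x OTUs matrix of nonnegative integer
#' read counts, with unique sample and OTU identifiers carried as dimnames.
#' It is the central object consumed by the diversity and distance stages.
#'
#' @param counts Integer matrix, samples in rows and OTUs in columns, with
#'   rownames (sample ids) and colnames (OTU ids).
#' @return An object of class `community_table` (a list with element
#'   `counts`).
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 4L, 1L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("otu1", "otu2", "otu3")))
#' community_table(m)
#' @export
community_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must carry sample rownames and OTU colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("sample ids must be unique", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("OTU ids must be unique", call. = FALSE)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(counts) == 0))
    stop("every retained sample must have a positive library size",
         call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts), class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d samples x %d OTUs, total reads %d\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Sample and OTU identifiers of a community table
#' @param x A `community_table`.
#' @return Character vector of identifiers.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname sample_ids
#' @export
otu_ids <- function(x) colnames(x$counts)

#' Read a mothur-style shared file
#'
#' Parses the tab-delimited `.shared` exchange format (columns `label`,
#' `Group`, `numOtus`, then one column per OTU). A single OTU-definition
#' label is required; files mixing labels are rejected.
#'
#' @param path Path to a `.shared` file.
#' @return A [community_table()].
#' @export
read_shared <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 4L || header[1] != "label" || header[2] != "Group" ||
      header[3] != "numOtus")
    stop("malformed .shared header: expected 'label\\tGroup\\tnumOtus\\t<OTUs...>'",
         call. = FALSE)
  otus <- header[-(1:3)]
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          rep("numeric", length(otus))))
  if (ncol(dat) != length(otus) + 3L)
    stop("malformed .shared file: ragged rows", call. = FALSE)
  if (length(unique(dat$label)) != 1L)
    stop("multiple `label` values in .shared file; a single OTU definition is expected",
         call. = FALSE)
  if (any(dat$numOtus != length(otus)))
    stop(sprintf("numOtus column disagrees with the %d OTU columns present",
                 length(otus)), call. = FALSE)
  m <- as.matrix(dat[, -(1:3), drop = FALSE])
  if (anyNA(m) || any(m < 0) || any(m != round(m)))
    stop("counts must be nonnegative integers", call. = FALSE)
  rownames(m) <- dat$Group
  community_table(m)
}

#' Write a community table as a mothur-style shared file
#'
#' @param x A `community_table`.
#' @param path Output path.
#' @param label OTU-definition label written in the first column.
#' @return Invisibly, `path`.
#' @export
write_shared <- function(x, path, label = "0.03") {
  m <- x$counts
  df <- data.frame(label = label, Group = rownames(m), numOtus = ncol(m),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a taxonomy map
#'
#' Maps each OTU to an ordered lineage over the canonical ranks
#' kingdom..genus. Unclassified tail ranks are encoded as
#' `unclassified_<nearest classified parent>` so that aggregation to any
#' rank is total.
#'
#' @param otu_id Character vector of OTU identifiers.
#' @param lineage Character vector of semicolon-delimited lineages, one per
#'   OTU; optional bootstrap-confidence suffixes `"(NN)"` are stripped.
#' @return Object of class `taxonomy_map`: a data.frame with columns
#'   `otu_id` and one per canonical rank.
#' @export
taxonomy_map <- function(otu_id, lineage) {
  if (length(otu_id) != length(lineage))
    stop("otu_id and lineage must have the same length", call. = FALSE)
  if (anyDuplicated(otu_id)) stop("duplicate otu_id", call. = FALSE)
  clean <- gsub("\\([0-9.]+\\)", "", lineage)
  clean <- sub(";\\s*$", "", clean)
  parts <- strsplit(clean, ";", fixed = TRUE)
  fill <- function(p) {
    p <- trimws(p)
    p <- p[nzchar(p)]
    out <- character(length(TAX_RANKS))
    parent <- "root"
    for (i in seq_along(TAX_RANKS)) {
      v <- if (i <= length(p)) p[i] else ""
      if (!nzchar(v) || identical(v, "unclassified"))
        v <- paste0("unclassified_", parent)
      out[i] <- v
      if (!startsWith(v, "unclassified_")) parent <- v
    }
    out
  }
  ranks <- t(vapply(parts, fill, character(length(TAX_RANKS))))
  colnames(ranks) <- TAX_RANKS
  structure(data.frame(otu_id = otu_id, ranks, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("taxonomy_map", "data.frame"))
}

#' Read / write a two-column taxonomy TSV
#'
#' Column 1 is the OTU id, column 2 the semicolon-delimited lineage. A
#' header line whose first field is `OTU` or `otu_id` is skipped.
#'
#' @param path File path.
#' @return [taxonomy_map()] for `read_taxonomy`; invisibly `path` for
#'   `write_taxonomy`.
#' @export
read_taxonomy <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  has_header <- tolower(first[1]) %in% c("otu", "otu_id")
  dat <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(dat) < 2L) stop("taxonomy file needs two columns", call. = FALSE)
  taxonomy_map(dat[[1]], dat[[ncol(dat)]])
}

#' @rdname read_taxonomy
#' @param tax A `taxonomy_map`.
#' @export
write_taxonomy <- function(tax, path) {
  lineage <- apply(as.matrix(tax[, TAX_RANKS]), 1L, paste, collapse = ";")
  utils::write.table(
    data.frame(otu_id = tax$otu_id, lineage = paste0(lineage, ";")),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct sample metadata
#'
#' Per-sample experimental coordinates for the 6-vessel, 2-condition,
#' 4-day design: vessel, condition, sampling day (1-4), hours post feeding
#' (4, 12 or 24) and hours since the start of the experiment. The
#' consistency constraint `time_h = 24 * (day - 1) + hours_post_feeding`
#' is enforced, as are uniqueness of (vessel, time_h) and constancy of
#' condition within vessel.
#'
#' @param df data.frame with columns `sample_id`, `vessel`, `condition`,
#'   `day`, `hours_post_feeding`, `time_h`.
#' @return Object of class `sample_metadata` (a data.frame).
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "vessel", "condition", "day", "hours_post_feeding",
            "time_h")
  if (!all(need %in% names(df)))
    stop("metadata must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[, need]
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id", call. = FALSE)
  if (!all(df$condition %in% c("control", "treatment")))
    stop("condition must be 'control' or 'treatment'", call. = FALSE)
  if (anyDuplicated(df[, c("vessel", "time_h")]))
    stop("(vessel, time_h) must be unique", call. = FALSE)
  by_vessel <- tapply(df$condition, df$vessel,
                      function(v) length(unique(v)))
  if (any(by_vessel > 1L))
    stop("condition must be constant within a vessel", call. = FALSE)
  if (!all(df$hours_post_feeding %in% c(4, 12, 24)))
    stop("hours_post_feeding must be 4, 12 or 24", call. = FALSE)
  if (any(df$time_h != 24 * (df$day - 1) + df$hours_post_feeding))
    stop("time_h must equal 24*(day-1) + hours_post_feeding", call. = FALSE)
  structure(df, class = c("sample_metadata", "data.frame"))
}

#' Read / write sample metadata TSV
#' @param path File path.
#' @return [sample_metadata()] for `read_metadata`.
#' @export
read_metadata <- function(path) {
  sample_metadata(utils::read.table(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE))
}

#' @rdname read_metadata
#' @param md A `sample_metadata`.
#' @export
write_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Validate a square symmetric dissimilarity matrix with ids as dimnames.
check_dist_matrix <- function(d, range01 = TRUE) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    stop("distance matrix must carry matching row/col ids", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12)
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  if (range01 && (min(d) < -1e-12 || max(d) > 1 + 1e-12))
    stop("distances must lie in [0, 1]", call. = FALSE)
  invisible(d)
}

#' Read / write a PHYLIP square distance matrix
#'
#' First line: the number of samples; each following line: sample id then
#' n dissimilarities.
#'
#' @param path File path.
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
read_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 1L)
    stop("malformed PHYLIP distance file", call. = FALSE)
  parts <- strsplit(trimws(lines[2:(n + 1L)]), "[ \t]+")
  ids <- vapply(parts, `[`, "", 1L)
  d <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(n)))
  dimnames(d) <- list(ids, ids)
  check_dist_matrix(d, range01 = FALSE)
  d
}

#' @rdname read_dist
#' @param d Symmetric distance matrix with ids as dimnames.
#' @export
write_dist <- function(d, path) {
  check_dist_matrix(d, range01 = FALSE)
  rows <- vapply(seq_len(nrow(d)), function(i) {
    paste(c(rownames(d)[i], formatC(d[i, ], digits = 12, format = "g")),
          collapse = "\t")
  }, "")
  writeLines(c(as.character(nrow(d)), rows), path)
  invisible(path)
}

#' Aggregate OTU counts to a taxonomic rank
#'
#' Sums counts of all OTUs sharing the same taxon name at the requested
#' rank. Per-sample totals are preserved exactly.
#'
#' @param x A `community_table`.
#' @param tax A `taxonomy_map` covering every OTU in `x`.
#' @param rank One of kingdom, phylum, class, order, family, genus.
#' @return A `community_table` whose columns are taxon names at `rank`.
#' @export
aggregate_to_rank <- function(x, tax, rank) {
  if (!rank %in% TAX_RANKS)
    stop("unknown rank '", rank, "'; must be one of ",
         paste(TAX_RANKS, collapse = ", "), call. = FALSE)
  m <- match(otu_ids(x), tax$otu_id)
  if (anyNA(m))
    stop("unmapped OTUs in taxonomy: ",
         paste(utils::head(otu_ids(x)[is.na(m)], 5L), collapse = ", "),
         call. = FALSE)
  groups <- tax[[rank]][m]
  agg <- t(rowsum(t(x$counts), group = groups))
  community_table(agg)
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly `depth` reads. Samples whose library size is
#' below `depth` are dropped with a warning.
#'
#' @param x A `community_table`.
#' @param depth Positive integer target depth.
#' @param seed Optional integer seed; the draw is reproducible given it.
#' @return A `community_table` with every row summing to `depth`.
#' @export
rarefy <- function(x, depth, seed = NULL) {
  if (length(depth) != 1L || is.na(depth) || depth <= 0 ||
      depth != round(depth))
    stop("`depth` must be a positive integer", call. = FALSE)
  depth <- as.integer(depth)
  rs <- rowSums(x$counts)
  low <- rs < depth
  if (any(low)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s", sum(low),
                    depth, paste(rownames(x$counts)[low], collapse = ", ")),
            call. = FALSE)
    if (all(low)) stop("no samples at or above depth", call. = FALSE)
  }
  m <- x$counts[!low, , drop = FALSE]
  out <- .with_seed(seed, {
    t(apply(m, 1L, function(row) {
      reads <- rep.int(seq_along(row), row)
      tabulate(sample(reads, depth), nbins = length(row))
    }))
  })
  dimnames(out) <- dimnames(m)
  community_table(out)
}

#' Remove singleton OTUs
#'
#' Drops OTUs whose total count across all samples equals 1, the standard
#' guard against spurious OTUs from residual sequencing error.
#'
#' @param x A `community_table`.
#' @return A `community_table` without singleton OTUs.
#' @export
filter_singletons <- function(x) {
  keep <- colSums(x$counts) != 1L
  community_table(x$counts[, keep, drop = FALSE])
}

# Run code under a temporary RNG seed, or under the ambient RNG if NULL.
.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Derive a reproducible child seed from a base seed and a stage index.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% 2147483647)
}
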