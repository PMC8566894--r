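#' Read an OTU count table
#'
#' Reads a tab-separated OTU table with a header row and an id column into the
#' canonical samples x taxa orientation. QIIME-classic tables (taxa as rows)
#' are the default; set `orientation = "samples-rows"` when samples are rows.
#'
#' @param path path to a TSV file whose first column holds ids.
#' @param orientation `"taxa-rows"` (default, QIIME classic) or
#'   `"samples-rows"`.
#' @return an integer matrix, samples as rows, taxa as columns, with dimnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(0:5, 2, 3, dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
#' write_otu_table(m, tf)
#' identical(read_otu_table(tf, orientation = "samples-rows"), m)
#' @export
read_otu_table <- function(path, orientation = c("taxa-rows", "samples-rows")) {
  orientation <- match.arg(orientation)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0 || ncol(tab) < 2) stop("empty or malformed OTU table: ", path)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate row ids in OTU table: ", path)
  if (anyDuplicated(colnames(tab)[-1])) stop("duplicate column ids in OTU table: ", path)
  body <- tab[, -1, drop = FALSE]
  num <- vapply(body, is.numeric, logical(1))
  if (!all(num)) stop("non-numeric cells in OTU table columns: ",
                      paste(colnames(body)[!num], collapse = ", "))
  m <- as.matrix(body)
  rownames(m) <- ids
  if (any(abs(m - round(m)) > 1e-8)) stop("non-integer counts in OTU table")
  m <- round(m)
  storage.mode(m) <- "integer"
  if (orientation == "taxa-rows") m <- t(m)
  check_community(m)
  m
}

#' Write an OTU count table
#'
#' @param m samples x taxa count matrix.
#' @param path output file.
#' @param orientation orientation to write; default taxa as rows
#'   (QIIME classic).
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(m, path, orientation = c("taxa-rows", "samples-rows")) {
  orientation <- match.arg(orientation)
  check_community(m)
  out <- if (orientation == "taxa-rows") t(m) else m
  id_name <- if (orientation == "taxa-rows") "otu_id" else "sample_id"
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c(id_name, colnames(out)), collapse = "\t"), con, sep = "\n")
  for (i in seq_len(nrow(out)))
    writeLines(paste(c(rownames(out)[i], out[i, ]), collapse = "\t"), con, sep = "\n")
  invisible(path)
}

#' Read a rooted phylogeny from a newick file
#'
#' Wraps [ape::read.tree()] with the checks the downstream phylogenetic
#' operations rely on: unique tip labels and branch lengths present and
#' non-negative.
#'
#' @param path newick file.
#' @return an [ape] `phylo` object.
#' @export
read_phylogeny <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) stop("could not read newick tree from ", path)
  validate_phylogeny(tree)
}

#' @rdname read_phylogeny
#' @param tree a `phylo` object to validate in place.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree
}

#' Patristic distances between tips
#'
#' @param tree a `phylo` object with branch lengths.
#' @return symmetric matrix of tip-to-tip path lengths.
#' @export
patristic_distances <- function(tree) {
  validate_phylogeny(tree)
  ape::cophenetic.phylo(tree)
}

#' Read or write sample metadata
#'
#' Metadata is a CSV with a `sample_id` column; remaining columns are
#' environmental variables (numeric) or group labels (character/factor).
#'
#' @param path CSV file.
#' @return a data.frame with a `sample_id` column.
#' @export
read_sample_metadata <- function(path) {
  env <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(env)) stop("metadata lacks a sample_id column")
  if (anyDuplicated(env$sample_id)) stop("duplicate sample ids in metadata")
  env
}

#' @rdname read_sample_metadata
#' @param env metadata data.frame.
#' @export
write_sample_metadata <- function(env, path) {
  stopifnot("sample_id" %in% colnames(env))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(env, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Rarefy a community matrix to even depth
#'
#' Subsamples each sample without replacement (multivariate hypergeometric) to
#' the requested depth, mirroring the normalization of amplicon libraries to a
#' common tag count. Samples whose total is below `depth` are dropped with a
#' warning. With `replace = TRUE` the draw is multinomial instead.
#'
#' @param m samples x taxa count matrix.
#' @param depth positive integer target depth.
#' @param seed optional integer seed; a fixed seed makes the draw
#'   bit-reproducible.
#' @param replace draw with replacement (default `FALSE`).
#' @return a count matrix whose rows each sum to `depth`.
#' @examples
#' m <- matrix(c(60L, 40L), 1, 2, dimnames = list("s1", c("a", "b")))
#' rowSums(rarefy_even_depth(m, 10, seed = 1))
#' @export
rarefy_even_depth <- function(m, depth, seed = NULL, replace = FALSE) {
  check_community(m)
  if (length(depth) != 1 || depth <= 0 || depth != round(depth))
    stop("depth must be a positive integer")
  totals <- rowSums(m)
  keep <- totals >= depth
  if (!any(keep)) stop("no sample reaches the requested depth")
  if (any(!keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(rownames(m)[!keep], collapse = ", "))
  m <- m[keep, , drop = FALSE]
  with_seed(seed, {
    out <- t(apply(m, 1, function(x) {
      if (replace) {
        as.vector(stats::rmultinom(1, depth, prob = x))
      } else if (sum(x) == depth) {
        x
      } else {
        pool <- rep.int(seq_along(x), x)
        drawn <- sample(pool, depth, replace = FALSE)
        tabulate(drawn, nbins = length(x))
      }
    }))
  })
  dimnames(out) <- dimnames(m)
  storage.mode(out) <- "integer"
  out
}
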