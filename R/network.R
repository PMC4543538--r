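#' Simulate a sparse signed TF-gene regulatory network
#'
#' Draws a random wiring diagram in which every gene is regulated by at least
#' one transcription factor. The number of regulators per gene follows a
#' Poisson distribution (mean `mean_regulators`) truncated below at 1 and
#' above at `n_tfs`; regulators are then sampled uniformly without
#' replacement. A fraction `frac_signed` of edges carries a known activation
#' (+1) or repression (-1) sign, drawn uniformly; the rest are of unknown
#' sign (0), mirroring the incomplete sign annotation of curated regulatory
#' databases.
#'
#' @param n_tfs Number of transcription factors.
#' @param n_genes Number of genes (must be >= `n_tfs`).
#' @param mean_regulators Mean number of regulators per gene (<= `n_tfs`).
#' @param frac_signed Fraction of edges with a known interaction sign.
#' @param seed Integer seed; identical seeds give identical networks.
#' @return A tibble with one row per regulatory edge and columns `tf`,
#'   `gene`, `sign` (integer in -1/0/+1, 0 meaning unknown).
#' @examples
#' net <- simulate_network(n_tfs = 3, n_genes = 20, mean_regulators = 1.5,
#'                         frac_signed = 0.5, seed = 1)
#' dplyr::count(net, tf)
#' @export
simulate_network <- function(n_tfs, n_genes, mean_regulators = 2,
                             frac_signed = 0.5, seed = 1) {
  n_tfs <- check_count(n_tfs, "n_tfs")
  n_genes <- check_count(n_genes, "n_genes")
  if (n_genes < n_tfs) abort("`n_genes` must be >= `n_tfs`.")
  check_scalar_number(mean_regulators, "mean_regulators", lower = 0,
                      strict_lower = TRUE)
  if (mean_regulators > n_tfs) {
    abort("`mean_regulators` must be <= `n_tfs`.")
  }
  check_scalar_number(frac_signed, "frac_signed", lower = 0, upper = 1)

  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))

  withr_seed(seed, {
    k <- pmin(pmax(rpois(n_genes, mean_regulators), 1L), n_tfs)
    edges <- purrr::map2(gene_ids, k, function(g, ki) {
      tibble(tf = sort(sample(tf_ids, ki)), gene = g)
    })
    edges <- dplyr::bind_rows(edges)
    n_e <- nrow(edges)
    signed <- runif(n_e) < frac_signed
    sgn <- integer(n_e)
    sgn[signed] <- sample(c(-1L, 1L), sum(signed), replace = TRUE)
    edges$sign <- sgn
  })
  dplyr::arrange(edges, .data$gene, .data$tf)
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% 2147483647L)
  eval.parent(substitute(expr))
}

#' Convert a network edge list to connectivity and sign matrices
#'
#' @param network Edge-list tibble as returned by [simulate_network()] or
#'   [read_network()].
#' @param gene_ids,tf_ids Optional orderings; default to the sorted sets
#'   present in the edge list.
#' @return A list with `connectivity` (genes x TFs binary matrix) and
#'   `signs` (same shape, entries -1/0/+1, nonzero only on edges).
#' @export
network_matrices <- function(network, gene_ids = NULL, tf_ids = NULL) {
  check_columns(network, c("tf", "gene", "sign"), "network")
  gene_ids <- gene_ids %||% sort(unique(network$gene))
  tf_ids <- tf_ids %||% sort(unique(network$tf))
  X <- matrix(0L, length(gene_ids), length(tf_ids),
              dimnames = list(gene_ids, tf_ids))
  S <- X
  idx <- cbind(match(network$gene, gene_ids), match(network$tf, tf_ids))
  if (anyNA(idx)) abort("network contains genes/TFs outside the given ids.")
  X[idx] <- 1L
  S[idx] <- as.integer(network$sign)
  list(connectivity = X, signs = S)
}

#' Read / write a signed TF-gene network file
#'
#' Tab-delimited with a header line and columns `TF`, `gene`, `sign`, where
#' sign is `+`, `-` or `?` (unknown), one edge per line -- the layout used by
#' regulonDB-style interaction exports.
#'
#' @param path File path.
#' @return `read_network()` returns the edge-list tibble (`tf`, `gene`,
#'   `sign` as -1/0/+1); `write_network()` returns `path` invisibly.
#' @export
read_network <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    TF = readr::col_character(), gene = readr::col_character(),
    sign = readr::col_character()
  ))
  bad <- setdiff(unique(df$sign), c("+", "-", "?"))
  if (length(bad) > 0L) {
    abort(sprintf("unknown sign code(s) in %s: %s", path,
                  paste(bad, collapse = ", ")))
  }
  tibble(tf = df$TF, gene = df$gene,
         sign = dplyr::case_match(df$sign, "+" ~ 1L, "-" ~ -1L, "?" ~ 0L))
}

#' @rdname read_network
#' @param network Edge-list tibble.
#' @export
write_network <- function(network, path) {
  check_columns(network, c("tf", "gene", "sign"), "network")
  out <- tibble(TF = network$tf, gene = network$gene,
                sign = c("-", "?", "+")[network$sign + 2L])
  readr::write_tsv(out, path)
  invisible(path)
}
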