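#' Generate a randomized resolvable incomplete block (alpha-type) layout
#'
#' Builds a plot layout in which every genotype appears exactly once per
#' replicate and each replicate is divided into `n_block` incomplete blocks of
#' equal size, as used in alpha designs for large diversity panels. Blocks are
#' laid on contiguous segments of a row-by-column grid, replicates on
#' contiguous bands, and genotypes are shuffled into blocks independently per
#' replicate. The construction aims at statistical validity of downstream
#' testing (resolvability, equal block sizes, unique plot coordinates), not at
#' agronomic optimality of the concurrence matrix.
#'
#' @param n_geno number of genotypes; must be divisible by `n_block`.
#' @param n_rep number of complete replicates.
#' @param n_block number of incomplete blocks per replicate.
#' @param grid_rows,grid_cols dimensions of the plot grid; the grid must hold
#'   at least `n_geno * n_rep` plots.
#' @param seed integer seed controlling the randomization.
#' @return a `trial_design`: a data frame with columns `plot_id`, `genotype`,
#'   `replicate`, `block`, `row`, `col`.
#' @examples
#' d <- make_design(48, 2, 12, 12, 8, seed = 1)
#' table(table(d$genotype))  # every genotype twice
#' @export
make_design <- function(n_geno, n_rep, n_block, grid_rows, grid_cols, seed) {
  if (n_geno %% n_block != 0) {
    stop_pp("`n_geno` (", n_geno, ") must be divisible by `n_block` (",
            n_block, ")")
  }
  n_plot <- n_geno * n_rep
  if (grid_rows * grid_cols < n_plot) {
    stop_pp("grid of ", grid_rows, " x ", grid_cols,
            " cannot hold ", n_plot, " plots")
  }
  block_size <- n_geno %/% n_block
  geno <- sprintf("G%03d", seq_len(n_geno))
  with_seed(seed, {
    rows <- integer(0); cols <- integer(0)
    genotype <- character(0); repl <- integer(0); block <- integer(0)
    for (j in seq_len(n_rep)) {
      g <- sample(geno)
      genotype <- c(genotype, g)
      repl <- c(repl, rep.int(j, n_geno))
      block <- c(block, rep(seq_len(n_block), each = block_size))
    }
    pos <- seq_len(n_plot)  # contiguous row-major fill
    design <- data.frame(
      plot_id = sprintf("P%04d", pos),
      genotype = genotype,
      replicate = repl,
      block = block,
      row = (pos - 1L) %/% grid_cols + 1L,
      col = (pos - 1L) %% grid_cols + 1L,
      stringsAsFactors = FALSE
    )
    class(design) <- c("trial_design", "data.frame")
    validate_design(design)
    design
  })
}

#' Validate a trial design
#'
#' Checks the structural invariants of a plot layout: unique plot ids and
#' (row, col) coordinates, every genotype replicated the same number of times,
#' equally sized blocks nested in replicates, and positive integer
#' coordinates.
#'
#' @param design a `trial_design` or equivalent data frame.
#' @return the design, invisibly; errors describe the violated invariant.
#' @export
validate_design <- function(design) {
  need <- c("plot_id", "genotype", "replicate", "block", "row", "col")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop_pp("design lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$plot_id)) stop_pp("duplicated plot_id values")
  key <- paste(design$row, design$col)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    ids <- design$plot_id[key == d]
    stop_pp("duplicated grid coordinate (row, col) = (", gsub(" ", ", ", d),
            ") used by plots: ", paste(ids, collapse = ", "))
  }
  if (any(design$row < 1L) || any(design$col < 1L) ||
      any(design$row != as.integer(design$row)) ||
      any(design$col != as.integer(design$col))) {
    stop_pp("row/col must be positive integers")
  }
  cnt <- table(design$genotype)
  if (length(unique(cnt)) != 1L) {
    stop_pp("genotypes are not equally replicated")
  }
  bl <- table(design$replicate, design$block)
  if (length(unique(as.vector(bl))) != 1L) {
    stop_pp("blocks within replicates are not of equal size")
  }
  invisible(design)
}

#' @export
print.trial_design <- function(x, ...) {
  cat("trial_design:", length(unique(x$genotype)), "genotypes x",
      length(unique(x$replicate)), "replicates,",
      length(unique(x$block)), "blocks/replicate,",
      nrow(x), "plots on a", max(x$row), "x", max(x$col), "grid\n")
  NextMethod()
}
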