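#' Write a fragment table as long tab-separated text
#'
#' Columns: `run_id`, `fragment_id`, `peptide`, `protein`, `intensity`
#' (linear scale; missing values omitted).
#'
#' @param fragments a `fragment_table`.
#' @param path output path.
#' @export
write_fragment_table <- function(fragments, path) {
  x <- fragments$intensity
  long <- data.frame(
    run_id = rep(colnames(x), each = nrow(x)),
    fragment_id = rep(rownames(x), ncol(x)),
    peptide = rep(fragments$fragments$peptide, ncol(x)),
    protein = rep(fragments$fragments$protein, ncol(x)),
    intensity = as.vector(x))
  long <- long[!is.na(long$intensity), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a long fragment table written by [write_fragment_table()]
#'
#' @param path path to the tab-separated file.
#' @param runs optional run ids fixing the column order (runs without any
#'   observation are kept as all-missing columns).
#' @return A `fragment_table`.
#' @export
read_fragment_table <- function(path, runs = NULL) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  frag <- unique(long[, c("fragment_id", "peptide", "protein")])
  if (is.null(runs)) runs <- unique(long$run_id)
  x <- matrix(NA_real_, nrow(frag), length(runs),
              dimnames = list(frag$fragment_id, runs))
  x[cbind(match(long$fragment_id, frag$fragment_id),
          match(long$run_id, runs))] <- long$intensity
  structure(list(intensity = x, fragments = frag, truth = NULL),
            class = "fragment_table")
}

#' Write a numeric matrix as tab-separated text with row names
#' @param mat matrix with row and column names.
#' @param path output path.
#' @param id_col name of the first (identifier) column.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "protein") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path path to the tab-separated file.
#' @return Numeric matrix with row names from the first column.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
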