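#' Construct and validate a pedigree
#'
#' A pedigree is a generation-ordered table of animals with their sire and
#' dam. Unknown parents may be given as `NA`, the empty string or `"0"`
#' (common pedigree-file dialects); all three are normalised to `NA`
#' internally.
#'
#' Validity requires unique animal ids, every named parent recorded as an
#' animal on an earlier row (which also guarantees acyclicity), and no animal
#' acting as its own parent.
#'
#' @param animal character vector of animal ids.
#' @param sire,dam character vectors of parent ids (`NA`, `""` or `"0"` for
#'   unknown), same length as `animal`.
#' @return A `data.frame` of class `td_pedigree` with character columns
#'   `animal`, `sire`, `dam` (unknown parents `NA`).
#' @examples
#' ped <- pedigree(c("S", "D", "O"), c(NA, NA, "S"), c(NA, NA, "D"))
#' build_a_matrix(ped)
#' @export
pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- normalize_parent(sire)
  dam <- normalize_parent(dam)
  if (length(sire) != length(animal) || length(dam) != length(animal)) {
    stop("'animal', 'sire' and 'dam' must have equal length")
  }
  ped <- data.frame(animal = animal, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  validate_pedigree(ped)
  class(ped) <- c("td_pedigree", "data.frame")
  ped
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "0" | x == "NA")] <- NA_character_
  x
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$animal)) {
    dup <- ped$animal[duplicated(ped$animal)][1L]
    stop("duplicated animal id in pedigree: '", dup, "'")
  }
  seen <- character(0)
  for (j in seq_len(nrow(ped))) {
    for (p in c(ped$sire[j], ped$dam[j])) {
      if (is.na(p)) next
      if (p == ped$animal[j]) {
        stop("animal '", ped$animal[j], "' is recorded as its own parent")
      }
      if (!(p %in% seen)) {
        stop("parent '", p, "' of animal '", ped$animal[j],
             "' does not appear as an earlier animal record; ",
             "pedigree must be generation-ordered and acyclic")
      }
    }
    seen <- c(seen, ped$animal[j])
  }
  invisible(ped)
}

#' Numerator relationship matrix by the tabular method
#'
#' Computes the additive (numerator) relationship matrix A by the tabular
#' recurrence: for animal j with parents s and d,
#' `a_ij = 0.5 * (a_is + a_id)` for earlier animals i, and
#' `a_jj = 1 + 0.5 * a_sd`. Unknown parents contribute zero, so founders are
#' unrelated and non-inbred. Inbreeding is handled exactly; no approximation
#' is made.
#'
#' @param ped a [pedigree()].
#' @return A symmetric numeric matrix with animal ids as dimnames. Diagonal
#'   entries are `1 + F_j` (F the inbreeding coefficient); all entries lie in
#'   `[0, 2]` and the matrix is positive semidefinite.
#' @export
build_a_matrix <- function(ped) {
  if (!inherits(ped, "td_pedigree")) {
    ped <- pedigree(ped$animal, ped$sire, ped$dam)
  }
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    A[j, j] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
    if (j > 1L) {
      i <- seq_len(j - 1L)
      as_ <- if (s > 0L) A[i, s] else 0
      ad_ <- if (d > 0L) A[i, d] else 0
      v <- 0.5 * (as_ + ad_)
      A[i, j] <- v
      A[j, i] <- v
    }
  }
  A
}

#' Synthetic paternal half-sib pedigree
#'
#' Generates a two-generation pedigree mirroring a progeny-testing herd:
#' `n_sires` unrelated founder sires and `n_dams` recorded cows, each cow
#' assigned a sire uniformly at random (multinomial allocation) with dam
#' unknown. The study-scale structure (82 sires, 464 cows) gives an average
#' of 464/82 = 5.66 daughters per sire.
#'
#' @param n_sires,n_dams positive counts with `n_dams >= n_sires`.
#' @param seed optional integer seed; identical seeds reproduce the pedigree.
#' @return a [pedigree()]; sires are `S1..Sn`, cows `C1..Cn`.
#' @export
synthetic_pedigree <- function(n_sires, n_dams, seed = NULL) {
  if (n_sires < 1 || n_dams < 1) stop("counts must be positive")
  if (n_dams < n_sires) stop("'n_dams' must be at least 'n_sires'")
  if (!is.null(seed)) set.seed(seed)
  sires <- paste0("S", seq_len(n_sires))
  cows <- paste0("C", seq_len(n_dams))
  assigned <- sample(sires, n_dams, replace = TRUE)
  pedigree(animal = c(sires, cows),
           sire = c(rep(NA_character_, n_sires), assigned),
           dam = rep(NA_character_, n_sires + n_dams))
}

#' Founder animals of a pedigree
#'
#' @param ped a [pedigree()].
#' @return logical vector: `TRUE` where both parents are unknown.
#' @export
is_founder <- function(ped) {
  is.na(ped$sire) & is.na(ped$dam)
}
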