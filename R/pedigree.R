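#' Build a validated, sorted pedigree
#'
#' Validates a three-column pedigree (animal, sire, dam), inserts parents
#' that are referenced but never listed as founders, sorts it so that every
#' parent precedes its offspring, renumbers animals internally `1..n`, and
#' computes inbreeding coefficients and Mendelian-sampling variance scalers.
#'
#' @param df data.frame with at least three columns: animal id, sire id,
#'   dam id (in that order, or named `animal`, `sire`, `dam`).
#' @param unknown_code token marking an unknown parent; empty strings and
#'   `NA` are always treated as unknown. Default `"0"`.
#' @param quiet suppress the message listing auto-inserted founders.
#' @return An object of class `pedigree`: a data.frame with columns
#'   `id` (original label), `animal`, `sire`, `dam` (internal integer codes,
#'   0 = unknown), `F` (inbreeding coefficient) and `d` (Mendelian-sampling
#'   variance as a fraction of the additive variance). The internal code of
#'   each original id is available through `attr(ped, "id_map")`.
#' @examples
#' ped <- as_pedigree(data.frame(animal = c("S", "D", "O"),
#'                               sire   = c("0", "0", "S"),
#'                               dam    = c("0", "0", "D")))
#' inbreeding(ped)
#' @export
as_pedigree <- function(df, unknown_code = "0", quiet = FALSE) {
  if (ncol(df) < 3L) stop("pedigree needs three columns: animal, sire, dam")
  nm <- tolower(names(df))
  take <- function(col, pos) if (col %in% nm) df[[which(nm == col)[1L]]] else df[[pos]]
  animal <- trimws(as.character(take("animal", 1L)))
  sire   <- trimws(as.character(take("sire",   2L)))
  dam    <- trimws(as.character(take("dam",    3L)))

  unk <- function(x) is.na(x) | x == "" | x == unknown_code
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)]   <- NA_character_
  if (anyNA(animal) || any(animal == "")) stop("missing animal id")
  if (anyDuplicated(animal)) {
    stop("duplicate animal id: ", paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  if (any(animal == sire, na.rm = TRUE) || any(animal == dam, na.rm = TRUE)) {
    stop("cycle: animal listed as its own parent")
  }

  # parents referenced but never listed become founders
  extra <- setdiff(c(sire, dam), c(animal, NA_character_))
  if (length(extra)) {
    if (!quiet) {
      message("inserted ", length(extra), " referenced parent(s) as founder(s): ",
              paste(utils::head(extra, 10L), collapse = ", "),
              if (length(extra) > 10L) ", ..." else "")
    }
    animal <- c(animal, extra)
    sire   <- c(sire, rep(NA_character_, length(extra)))
    dam    <- c(dam,  rep(NA_character_, length(extra)))
  }

  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam),  0L, idx[dam])

  # Kahn topological sort; a leftover node means a cycle through ancestors
  indeg <- integer(n)
  child <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        child[[p]] <- c(child[[p]], i)
      }
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (w in child[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) < n) {
    stop("cycle: animal is its own ancestor (", paste(animal[setdiff(idx, order)], collapse = ", "), ")")
  }

  pos <- integer(n)          # old index -> new index
  pos[order] <- seq_len(n)
  newsire <- ifelse(si[order] > 0L, pos[pmax(si[order], 1L)], 0L)
  newdam  <- ifelse(di[order] > 0L, pos[pmax(di[order], 1L)], 0L)
  fd <- .inbreeding_ml(newsire, newdam)

  ped <- data.frame(id = animal[order], animal = seq_len(n),
                    sire = newsire, dam = newdam,
                    F = fd$F, d = fd$D, stringsAsFactors = FALSE)
  id_map <- stats::setNames(seq_len(n), animal[order])
  structure(ped, id_map = id_map, class = c("pedigree", "data.frame"))
}

#' Read a pedigree file
#'
#' Reads a 3-column delimited pedigree (animal, sire, dam). The delimiter is
#' auto-detected among comma, tab and semicolon, and a header line is
#' detected by matching the column names.
#'
#' @inheritParams as_pedigree
#' @param path path to the pedigree file.
#' @return A sorted [as_pedigree()] object.
#' @export
read_pedigree <- function(path, unknown_code = "0", quiet = FALSE) {
  first <- readLines(path, n = 1L)
  sep <- c(",", "\t", ";")[which.max(c(
    lengths(regmatches(first, gregexpr(",", first, fixed = TRUE))),
    lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE))),
    lengths(regmatches(first, gregexpr(";", first, fixed = TRUE)))))]
  toks <- gsub("[\"']", "", tolower(trimws(strsplit(first, sep, fixed = TRUE)[[1L]])))
  header <- any(c("animal", "sire", "dam", "id") %in% toks)
  df <- utils::read.table(path, sep = sep, header = header,
                          colClasses = "character", strip.white = TRUE)
  as_pedigree(df, unknown_code = unknown_code, quiet = quiet)
}

# Diagonal of A without forming A (Meuwissen & Luo style ancestor sweep).
# Returns F (inbreeding) and D (Mendelian-sampling variance scaler):
#   both parents known  d = 0.5 - 0.25 (F_s + F_d)
#   one parent known    d = 0.75 - 0.25 F_p
#   no parent known     d = 1
.inbreeding_ml <- function(sire, dam) {
  n <- length(sire)
  F <- numeric(n)
  D <- numeric(n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    Fs <- if (s > 0L) F[s] else -1
    Fd <- if (d > 0L) F[d] else -1
    D[i] <- 0.5 - 0.25 * (Fs + Fd)
    if (s == 0L || d == 0L) next   # F stays 0
    L <- numeric(i)
    L[i] <- 1
    act <- i
    aii <- 0
    while (length(act)) {
      j <- max(act)
      act <- act[act != j]
      lj <- L[j]
      aii <- aii + lj * lj * D[j]
      sj <- sire[j]; dj <- dam[j]
      if (sj > 0L) { if (L[sj] == 0) act <- c(act, sj); L[sj] <- L[sj] + 0.5 * lj }
      if (dj > 0L) { if (L[dj] == 0) act <- c(act, dj); L[dj] <- L[dj] + 0.5 * lj }
    }
    F[i] <- aii - 1
  }
  list(F = F, D = D)
}

#' Inbreeding coefficients
#'
#' @param ped a [as_pedigree()] object.
#' @return Named numeric vector of inbreeding coefficients `F`, one per
#'   animal, in pedigree order (names are original ids).
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  stats::setNames(ped$F, ped$id)
}

#' Dense numerator relationship matrix A
#'
#' Builds A by the tabular method. Intended for small and medium pedigrees
#' (oracles and simulation); a size guard protects against accidental dense
#' builds on large pedigrees.
#'
#' @param ped a [as_pedigree()] object.
#' @param max_n size guard; refuse to build a dense matrix beyond this
#'   number of animals. Default 5000.
#' @return Dense symmetric matrix with `dimnames` set to the original ids;
#'   `diag(A) == 1 + F`.
#' @export
relationship_matrix <- function(ped, max_n = 5000L) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  if (n > max_n) {
    stop("pedigree has ", n, " animals; dense A capped at max_n = ", max_n)
  }
  A <- matrix(0, n, n)
  sire <- ped$sire; dam <- ped$dam
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[s, j]
      if (d > 0L) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds the inverse of A directly from the pedigree by Henderson's rules
#' with the inbreeding adjustment: each animal contributes
#' `alpha = 1/d` to its own diagonal, `-alpha/2` to animal-parent cells and
#' `alpha/4` to parent-parent cells, where `d` is the Mendelian-sampling
#' variance (terms for unknown parents are dropped).
#'
#' @param ped a [as_pedigree()] object.
#' @return Sparse symmetric `Matrix::dsCMatrix` with original ids as
#'   dimnames.
#' @export
a_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  sire <- ped$sire; dam <- ped$dam
  alpha <- 1 / ped$d
  nk <- (sire > 0L) + (dam > 0L)
  m <- sum(1L + 2L * nk + nk * nk)
  ii <- integer(m); jj <- integer(m); xx <- numeric(m)
  k <- 0L
  for (i in seq_len(n)) {
    a <- alpha[i]
    par <- c(sire[i], dam[i])
    par <- par[par > 0L]
    k <- k + 1L; ii[k] <- i; jj[k] <- i; xx[k] <- a
    for (p in par) {
      k <- k + 1L; ii[k] <- i; jj[k] <- p; xx[k] <- -a / 2
      k <- k + 1L; ii[k] <- p; jj[k] <- i; xx[k] <- -a / 2
      for (q in par) {
        k <- k + 1L; ii[k] <- p; jj[k] <- q; xx[k] <- a / 4
      }
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii[1:k], j = jj[1:k], x = xx[1:k],
                               dims = c(n, n), dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(Ainv)
}

# log det(A) from a sparse A-inverse (used by the REML criterion)
.logdet_A_from_inv <- function(Ainv) {
  -as.numeric(Matrix::determinant(Ainv, logarithm = TRUE)$modulus)
}
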