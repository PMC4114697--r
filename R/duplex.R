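# Intermolecular RNA-RNA duplex free energy.
#
# Minimum free energy over all antiparallel, non-crossing pairings of
# two RNA strands (both given 5'->3'), scored with a nearest-neighbor
# stack table, a duplex initiation penalty, and an affine penalty for
# interior/bulge loops -- the intermolecular-only model of
# RNAduplex-style programs.  No intramolecular structure, dangling
# ends, or partition function.  A brute-force enumerator over the same
# scoring serves as the exact oracle for small inputs.

.DUPLEX_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Duplex scoring parameters
#'
#' Loads the bundled nearest-neighbor stack table (Watson-Crick + G:U)
#' and combines it with the duplex initiation penalty and the affine
#' interior/bulge-loop penalty `a + b * (n1 + n2)` for loops of side
#' sizes `(n1, n2) != (0, 0)` up to `loop_max` unpaired bases in total.
#'
#' @param init Duplex initiation penalty, kcal/mol (> 0).
#' @param loop_a,loop_b Affine loop penalty coefficients (>= 0).
#' @param loop_max Maximum total loop size between consecutive pairs.
#' @param stack_file Optional path to an alternative stack table (TSV
#'   with columns `pair1`, `pair2`, `dg`).
#' @return An object of class `duplex_params`.
#' @export
default_duplex_params <- function(init = 4.09, loop_a = 4.0, loop_b = 0.4,
                                  loop_max = 30L, stack_file = NULL) {
  if (is.null(stack_file)) {
    stack_file <- system.file("extdata", "nn_stacks.tsv", package = "srnaevo",
                              mustWork = TRUE)
  }
  tab <- utils::read.delim(stack_file, comment.char = "#",
                           stringsAsFactors = FALSE)
  stacks <- matrix(NA_real_, 6L, 6L,
                   dimnames = list(.DUPLEX_PAIRS, .DUPLEX_PAIRS))
  stacks[cbind(tab$pair1, tab$pair2)] <- tab$dg
  if (anyNA(stacks)) stop("incomplete stack table: ", stack_file)
  if (init <= 0) stop("duplex initiation penalty must be positive")
  if (loop_a < 0 || loop_b < 0) stop("loop penalty coefficients must be >= 0")
  structure(
    list(stacks = stacks, init = init, loop_a = loop_a, loop_b = loop_b,
         loop_max = as.integer(loop_max)),
    class = "duplex_params"
  )
}

#' Toy duplex parameters for exact hand computation
#'
#' Every admissible stack scores `stack`, initiation is `init`, and
#' loops are disallowed (`loop_a = Inf`), so the optimum is a maximal
#' run of contiguous pairs.
#'
#' @param stack Stack energy (default -2).
#' @param init Initiation penalty (default +4).
#' @return A `duplex_params` object.
#' @export
toy_duplex_params <- function(stack = -2, init = 4) {
  p <- default_duplex_params()
  p$stacks[] <- stack
  p$init <- init
  p$loop_a <- Inf
  p$loop_b <- 0
  p
}

.pair_key <- function(xa, xb) paste0(xa, xb)

.clean_rna <- function(x, arg) {
  x <- toupper(chartr("Tt", "Uu", x))
  if (grepl("[^ACGUN]", x)) {
    stop(arg, " contains characters outside {A, C, G, U, N}")
  }
  x
}

.step_energy <- function(params, pk_prev, pk, n1, n2) {
  if (n1 == 0L && n2 == 0L) return(params$stacks[pk_prev, pk])
  if (n1 + n2 > params$loop_max) return(Inf)
  params$loop_a + params$loop_b * (n1 + n2)
}

#' Minimum free energy of an intermolecular duplex
#'
#' Dynamic program over admissible pairs `(i, j)` of positions on the
#' two strands (both 5'->3'): pairs along a duplex run with `i`
#' increasing and `j` decreasing (antiparallel), consecutive pairs are
#' joined by a stack (contiguous) or by an affine interior/bulge loop,
#' and the duplex pays one initiation penalty.  `E[i, j]` is the best
#' energy of a duplex whose 3'-most pair on `seq_a` is `(i, j)`; the
#' answer is the minimum over all pairs.
#'
#' @param seq_a,seq_b RNA sequences 5'->3' over \{A, C, G, U, N\}
#'   (`T` is accepted and read as `U`; `N` never pairs).
#' @param params A [default_duplex_params()] object.
#' @return An object of class `duplex_result`: list with `energy`
#'   (kcal/mol, `NA` if no admissible pair exists), `no_duplex`
#'   (logical), `pairs` (two-column matrix of 1-based paired positions),
#'   and `a_interval`, `b_interval` (0-based half-open spans of the
#'   paired regions).
#' @export
duplex_energy <- function(seq_a, seq_b, params = default_duplex_params()) {
  seq_a <- .clean_rna(seq_a, "seq_a")
  seq_b <- .clean_rna(seq_b, "seq_b")
  a <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  b <- strsplit(seq_b, "", fixed = TRUE)[[1]]
  cand <- which(outer(a, b, function(x, y) .pair_key(x, y) %in% .DUPLEX_PAIRS),
                arr.ind = TRUE)
  if (nrow(cand) == 0) return(.no_duplex_result())
  # order by i ascending then j descending: all admissible predecessors
  # of a pair precede it in this order
  ord <- order(cand[, 1L], -cand[, 2L])
  pi <- cand[ord, 1L]
  pj <- cand[ord, 2L]
  pk <- .pair_key(a[pi], b[pj])
  np <- length(pi)
  E <- rep(params$init, np)
  back <- rep(NA_integer_, np)
  for (q in seq_len(np)) {
    preds <- which(pi < pi[q] & pj > pj[q])
    if (length(preds) > 0) {
      n1 <- pi[q] - pi[preds] - 1L
      n2 <- pj[preds] - pj[q] - 1L
      step <- ifelse(
        n1 == 0L & n2 == 0L,
        params$stacks[cbind(pk[preds], rep(pk[q], length(preds)))],
        ifelse(n1 + n2 > params$loop_max, Inf,
               params$loop_a + params$loop_b * (n1 + n2))
      )
      val <- E[preds] + step
      w <- which.min(val)
      if (val[w] < params$init) {
        E[q] <- val[w]
        back[q] <- preds[w]
      }
    }
  }
  best <- which.min(E)
  chain <- integer(0)
  q <- best
  while (!is.na(q)) {
    chain <- c(q, chain)
    q <- back[q]
  }
  pairs <- cbind(a = pi[chain], b = pj[chain])
  structure(
    list(
      energy = E[best], no_duplex = FALSE, pairs = pairs,
      a_interval = c(min(pairs[, "a"]) - 1L, max(pairs[, "a"])),
      b_interval = c(min(pairs[, "b"]) - 1L, max(pairs[, "b"]))
    ),
    class = "duplex_result"
  )
}

.no_duplex_result <- function() {
  structure(
    list(energy = NA_real_, no_duplex = TRUE,
         pairs = matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("a", "b"))),
         a_interval = NULL, b_interval = NULL),
    class = "duplex_result"
  )
}

#' @export
print.duplex_result <- function(x, ...) {
  if (x$no_duplex) {
    cat("No admissible duplex\n")
  } else {
    cat(sprintf("Duplex dG = %.2f kcal/mol over %d pair(s)\n",
                x$energy, nrow(x$pairs)))
  }
  invisible(x)
}

#' Brute-force duplex energy (exact oracle)
#'
#' Exhaustively enumerates every antiparallel non-crossing pair chain
#' under the same scoring as [duplex_energy()] and returns the best.
#' Exponential; restricted to `nchar(seq_a) * nchar(seq_b) <= 100`.
#'
#' @inheritParams duplex_energy
#' @return A `duplex_result` object.
#' @export
brute_force_duplex_energy <- function(seq_a, seq_b,
                                      params = default_duplex_params()) {
  seq_a <- .clean_rna(seq_a, "seq_a")
  seq_b <- .clean_rna(seq_b, "seq_b")
  if (nchar(seq_a) * nchar(seq_b) > 100) {
    stop("input too large for brute-force enumeration")
  }
  a <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  b <- strsplit(seq_b, "", fixed = TRUE)[[1]]
  cand <- which(outer(a, b, function(x, y) .pair_key(x, y) %in% .DUPLEX_PAIRS),
                arr.ind = TRUE)
  if (nrow(cand) == 0) return(.no_duplex_result())
  ci <- cand[, 1L]
  cj <- cand[, 2L]
  ck <- .pair_key(a[ci], b[cj])
  best <- Inf
  best_chain <- NULL
  recurse <- function(chain, energy) {
    last <- chain[length(chain)]
    if (energy < best) {
      best <<- energy
      best_chain <<- chain
    }
    nxt <- which(ci > ci[last] & cj < cj[last])
    for (q in nxt) {
      st <- .step_energy(params, ck[last], ck[q],
                         ci[q] - ci[last] - 1L, cj[last] - cj[q] - 1L)
      if (is.finite(st)) recurse(c(chain, q), energy + st)
    }
  }
  for (s in seq_along(ci)) recurse(s, params$init)
  pairs <- cbind(a = ci[best_chain], b = cj[best_chain])
  structure(
    list(
      energy = best, no_duplex = FALSE, pairs = pairs,
      a_interval = c(min(pairs[, "a"]) - 1L, max(pairs[, "a"])),
      b_interval = c(min(pairs[, "b"]) - 1L, max(pairs[, "b"]))
    ),
    class = "duplex_result"
  )
}

#' Call mRNA binding-site presence by the relative-energy rule
#'
#' An orthologous site is present iff the target-gene ortholog exists
#' in the genome, the extracted site has no alignment gap in its core
#' columns, and its duplex energy with the (orthologous or ancestral)
#' sRNA site reaches at least `ratio` of the stability of the reference
#' pairing: `dg_orth <= ratio * dg_ref` (both energies negative; the
#' boundary is inclusive).  A failed duplex (`NA` energy) is absent.
#'
#' @param dg_orth Duplex energy (kcal/mol) of the ortholog pairing, or
#'   `NA` when no duplex formed.  Vectorized.
#' @param dg_ref Duplex energy of the reference (focal-genome) pairing;
#'   must be negative.
#' @param ratio Required fraction of the reference stability
#'   (default 0.9).
#' @param gap_flag Logical: gap within the core site columns.
#' @param ortholog_present Logical: target-gene ortholog present.
#' @return Integer 0/1 vector of presence calls.
#' @export
mbs_call <- function(dg_orth, dg_ref, ratio = 0.9, gap_flag = FALSE,
                     ortholog_present = TRUE) {
  if (!is.finite(dg_ref) || dg_ref >= 0) {
    stop("reference duplex energy must be negative (stabilizing)")
  }
  n <- length(dg_orth)
  gap_flag <- rep_len(gap_flag, n)
  ortholog_present <- rep_len(ortholog_present, n)
  ok_energy <- !is.na(dg_orth) & dg_orth <= ratio * dg_ref + 1e-9
  as.integer(ortholog_present & !gap_flag & ok_energy)
}
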