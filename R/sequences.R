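# Charge-sequence generation and taxonomy: Markovian +/-1 sequences on the
# charged-site template, run-length block decomposition over charged sites,
# Table-style blockiness groups, and the central net charge (CNC).

#' Charged-site template of a polyampholyte chain
#'
#' Charges sit on both end monomers and on every third monomer: positions
#' 1, 4, 7, ... plus the final monomer. For the canonical 100-mer this gives
#' 34 charged sites.
#'
#' @param length Number of monomers (>= 2).
#' @return Integer vector of 1-based charged monomer positions.
#' @export
charged_positions <- function(length = 100) {
  if (length < 2) stop("length must be >= 2")
  sort(unique(c(seq(1L, length, by = 3L), length)))
}

new_pa_sequence <- function(charges, length) {
  pos <- charged_positions(length)
  q <- sum(charges)
  structure(list(
    length = length,
    charges = charges,
    charged_positions = pos,
    site_signs = charges[pos],
    net_charge = q,
    majority_sign = if (q != 0) sign(q) else NA_integer_,
    minority_sign = if (q != 0) -sign(q) else NA_integer_
  ), class = "pa_sequence")
}

#' Generate a random polyampholyte charge sequence
#'
#' Charged sites carry +1 or -1 drawn from a first-order Markov chain with
#' symmetric marginals (P(+) = P(-) = 1/2) and a nearest-charged-site
#' correlation coefficient `correlation`; `correlation = 0` (the default)
#' gives independent fair draws, so the ensemble average net charge is zero.
#'
#' @param length Number of monomers (default 100 gives 34 charged sites).
#' @param correlation Nearest-charged-site correlation, in (-1, 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A `pa_sequence`: per-monomer charges in \{-1, 0, +1\}, the charged
#'   positions, the net charge Q, and the majority/minority signs.
#' @examples
#' s <- generate_sequence(100, seed = 1)
#' s$net_charge
#' @export
generate_sequence <- function(length = 100, correlation = 0, seed = NULL) {
  if (!is.numeric(correlation) || abs(correlation) >= 1)
    stop("correlation must lie strictly inside (-1, 1)")
  if (!is.null(seed)) set.seed(seed)
  pos <- charged_positions(length)
  m <- base::length(pos)
  p_same <- (1 + correlation) / 2
  s <- integer(m)
  s[1] <- if (runif(1) < 0.5) 1L else -1L
  if (m > 1) {
    same <- runif(m - 1) < p_same
    for (i in 2:m) s[i] <- if (same[i - 1]) s[i - 1] else -s[i - 1]
  }
  charges <- integer(length)
  charges[pos] <- s
  new_pa_sequence(charges, length)
}

#' Select a fixed-net-charge ensemble from a random pool
#'
#' Generates `pool_size` random sequences and keeps those whose net charge
#' equals `target_q`, in generation order. With an even number of charged
#' sites Q is always even, so an odd target is rejected up front.
#'
#' @inheritParams generate_sequence
#' @param pool_size Number of sequences to draw.
#' @param target_q Required net charge.
#' @param max_keep Stop early after this many accepted sequences.
#' @return List of `pa_sequence` objects; the attribute
#'   `"acceptance_fraction"` records accepted / generated.
#' @export
select_q_ensemble <- function(pool_size, target_q, correlation = 0,
                              seed = NULL, length = 100, max_keep = Inf) {
  if (!is.null(seed)) set.seed(seed)
  m <- base::length(charged_positions(length))
  if ((m %% 2L) != (abs(target_q) %% 2L))
    stop("target_q = ", target_q, " has the wrong parity: with ", m,
         " unit charges the net charge must have the parity of ", m)
  if (abs(target_q) > m) stop("target_q exceeds the number of charged sites")
  out <- vector("list", min(pool_size, 4096))
  kept <- 0L
  for (i in seq_len(pool_size)) {
    s <- generate_sequence(length, correlation)
    if (s$net_charge == target_q) {
      kept <- kept + 1L
      if (kept > base::length(out)) out <- c(out, vector("list", base::length(out)))
      out[[kept]] <- s
      if (kept >= max_keep) {
        out <- out[seq_len(kept)]
        attr(out, "acceptance_fraction") <- kept / i
        attr(out, "n_generated") <- i
        return(out)
      }
    }
  }
  out <- out[seq_len(kept)]
  attr(out, "acceptance_fraction") <- kept / pool_size
  attr(out, "n_generated") <- pool_size
  out
}

#' Decompose a sequence into same-sign charge blocks
#'
#' Runs are computed over the charged-site subsequence only (the neutral
#' spacer monomers between charge sites are ignored), so a "block" is a
#' maximal run of equal-sign charges along the charged sites.
#'
#' @param seq A `pa_sequence` with nonzero net charge.
#' @return A `pa_blocks` list: the ordered `(sign, size)` runs, the minority
#'   block sizes (decreasing), the terminal majority run sizes at the head and
#'   tail of the chain (0 when a terminus starts with a minority charge), and
#'   a `single_block` flag for the degenerate all-one-sign case.
#' @export
decompose_blocks <- function(seq) {
  stopifnot(inherits(seq, "pa_sequence"))
  if (seq$net_charge == 0)
    stop("net charge is zero: minority sign undefined")
  r <- rle(seq$site_signs)
  blocks <- data.frame(sign = r$values, size = r$lengths)
  maj <- seq$majority_sign
  minority_sizes <- sort(blocks$size[blocks$sign == -maj], decreasing = TRUE)
  single <- nrow(blocks) == 1L
  head_run <- if (blocks$sign[1] == maj) blocks$size[1] else 0L
  tail_run <- if (blocks$sign[nrow(blocks)] == maj) blocks$size[nrow(blocks)] else 0L
  structure(list(
    blocks = blocks,
    minority_block_sizes = as.integer(minority_sizes),
    longest_minority = if (length(minority_sizes)) minority_sizes[1] else 0L,
    second_longest_minority = if (length(minority_sizes) > 1) minority_sizes[2] else 0L,
    terminal_majority_head = as.integer(head_run),
    terminal_majority_tail = as.integer(tail_run),
    net_charge = seq$net_charge,
    majority_sign = maj,
    single_block = single
  ), class = "pa_blocks")
}

group_letter <- function(lmax) {
  if (lmax >= 4) paste(rep("A", lmax - 3L), collapse = "")
  else if (lmax == 3) "B"
  else if (lmax == 2) "C"
  else "S" # isolated minority charges only
}

composition_label <- function(sizes) {
  if (!length(sizes)) return("none")
  t <- table(factor(sizes, levels = sort(unique(sizes), decreasing = TRUE)))
  paste(sprintf("(-%s)x%d", names(t), as.integer(t)), collapse = ",")
}

#' Classify a sequence by the blockiness of its minority charges
#'
#' Group labels follow the canonical taxonomy for the Q = 8 ensemble: the
#' longest minority block of size 6/5 gives AAA/AA; size 4 occurring twice
#' gives A2 and once gives A1 (split into the subgroups `(-4)x1,(-3)x1` when
#' a triplet is present and `(-4)x1,(-2)xn` otherwise); size 3 with
#' multiplicity 3/2/1 gives B3/B2/B1; size 2 with multiplicity 5/4/3 gives
#' C5/C4/C3. Multiplicities outside the taxonomy get systematic fallback
#' labels (e.g. C2, B4) flagged `in_taxonomy = FALSE`.
#'
#' @param dec A `pa_blocks` decomposition (see [decompose_blocks()]).
#' @return A list with `group_label`, `subgroup_label`, `composition`,
#'   `cnc` (central net charge), and `in_taxonomy`.
#' @export
classify_group <- function(dec) {
  stopifnot(inherits(dec, "pa_blocks"))
  sizes <- dec$minority_block_sizes
  lmax <- dec$longest_minority
  n_lmax <- sum(sizes == lmax)
  letter <- group_letter(lmax)
  known <- FALSE
  if (lmax >= 5) {
    label <- letter
    known <- n_lmax == 1L
    if (!known) label <- paste0(letter, n_lmax)
  } else if (lmax == 4) {
    label <- paste0("A", n_lmax)
    known <- n_lmax %in% c(1L, 2L)
  } else if (lmax == 3) {
    label <- paste0("B", n_lmax)
    known <- n_lmax %in% 1:3
  } else if (lmax == 2) {
    label <- paste0("C", n_lmax)
    known <- n_lmax %in% 3:5
  } else {
    label <- paste0("S", max(n_lmax, 0L))
  }
  sub <- composition_label(sizes)
  if (label == "A1") {
    sub <- if (any(sizes == 3)) "(-4)x1,(-3)x1" else "(-4)x1,(-2)xn"
  }
  list(group_label = label,
       subgroup_label = sub,
       composition = composition_label(sizes),
       cnc = central_net_charge(dec),
       in_taxonomy = known)
}

#' Central net charge of a sequence
#'
#' The net charge that remains after excluding the majority-type charges of
#' the first block at each chain end: `CNC = Q - head - tail`, where a
#' terminus whose first charged site carries the minority sign contributes 0.
#' A small (or negative) CNC marks a weakly charged core once the majority
#' tails are peeled off, which stabilizes the dimer.
#'
#' @param dec A `pa_blocks` decomposition.
#' @return Integer CNC. For the degenerate single-block sequence the whole
#'   block is treated as both head and tail once, returning Q minus that
#'   block with a warning.
#' @export
central_net_charge <- function(dec) {
  stopifnot(inherits(dec, "pa_blocks"))
  if (dec$single_block) {
    warning("single-block sequence: CNC convention returns Q minus the block")
    return(as.integer(dec$net_charge -
                      dec$majority_sign * dec$blocks$size[1]))
  }
  as.integer(dec$net_charge - dec$terminal_majority_head -
             dec$terminal_majority_tail)
}

#' Tabulate descriptors for an ensemble of sequences
#'
#' @param seqs List of `pa_sequence` objects.
#' @return A data frame with columns `id`, `Q`, `group`, `subgroup`,
#'   `minority_blocks`, `cnc`, `longest`, `n_longest`, `in_taxonomy`.
#' @export
describe_sequences <- function(seqs) {
  rows <- lapply(seq_along(seqs), function(i) {
    dec <- decompose_blocks(seqs[[i]])
    cl <- classify_group(dec)
    data.frame(id = i, Q = seqs[[i]]$net_charge, group = cl$group_label,
               subgroup = cl$subgroup_label,
               minority_blocks = cl$composition, cnc = cl$cnc,
               longest = dec$longest_minority,
               n_longest = sum(dec$minority_block_sizes == dec$longest_minority),
               in_taxonomy = cl$in_taxonomy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
format.pa_sequence <- function(x, ...) {
  chr <- c("-", "0", "+")[x$charges + 2L]
  paste(chr, collapse = "")
}

#' @export
print.pa_sequence <- function(x, ...) {
  cat("<pa_sequence> N =", x$length, " charged =",
      length(x$charged_positions), " Q =", x$net_charge, "\n")
  cat(format(x), "\n")
  invisible(x)
}

#' Parse a sequence from its +/-/0 string form
#'
#' @param s Character string over \{+, -, 0\}, one character per monomer.
#' @return A `pa_sequence`.
#' @export
parse_sequence <- function(s) {
  chars <- strsplit(s, "")[[1]]
  if (!all(chars %in% c("+", "-", "0"))) stop("sequence string must use +, -, 0")
  charges <- c("-" = -1L, "0" = 0L, "+" = 1L)[chars]
  names(charges) <- NULL
  pos <- charged_positions(length(charges))
  if (!identical(which(charges != 0L), pos))
    stop("charges must occupy exactly the charged-site template positions")
  new_pa_sequence(charges, length(charges))
}

#' Write sequences to a FASTA-like text file
#'
#' One record per sequence; the header carries the net charge, group label
#' and CNC, the body is the +/-/0 string.
#'
#' @param seqs List of `pa_sequence`.
#' @param path Output file.
#' @export
write_sequences_fasta <- function(seqs, path) {
  desc <- describe_sequences(seqs)
  lines <- unlist(lapply(seq_along(seqs), function(i) {
    c(sprintf(">seq%d Q=%d group=%s CNC=%d", i, desc$Q[i], desc$group[i],
              desc$cnc[i]),
      format(seqs[[i]]))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from the FASTA-like format of [write_sequences_fasta()]
#'
#' @param path Input file.
#' @return List of `pa_sequence`.
#' @export
read_sequences_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  lapply(hdr, function(h) parse_sequence(lines[h + 1]))
}
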