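# Fold candidate windows and apply the eleven secondary-structure criteria
# used to accept novel miRNA hairpins.
#
# Backends: "builtin" is a maximum-pairing dynamic program (minimum loop 3,
# G.U wobble allowed) with a crude stacking-energy estimate, labeled
# approximate; "file" is a pass-through for externally computed Vienna-style
# structures (the test-suite default, and the bypass for an external folding
# engine).

can_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
  (a == "G" & b == "C") | (a == "C" & b == "G") |
  (a == "G" & b == "T") | (a == "T" & b == "G")
}

# crude per-pair stability estimate, kcal/mol
pair_energy <- function(a, b) {
  ifelse((a == "G" & b == "C") | (a == "C" & b == "G"), -3,
  ifelse((a == "A" & b == "T") | (a == "T" & b == "A"), -2, -1))
}

# Nussinov-style maximum-pairing DP; returns list(pairs = 2-col matrix of
# 1-based (i, j), n_pairs). Minimum hairpin loop of 3 unpaired bases.
nussinov_fold <- function(sequence, min_loop = 3L) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  M <- matrix(0L, n, n)
  if (n >= min_loop + 2L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in 1:(n - span)) {
        j <- i + span
        best <- max(M[i + 1L, j], M[i, j - 1L])
        if (can_pair(ch[i], ch[j])) best <- max(best, M[i + 1L, j - 1L] + 1L)
        ks <- (i + 1L):(j - 1L)
        if (length(ks)) {
          vals <- M[cbind(i, ks)] + M[cbind(ks + 1L, j)]
          best <- max(best, max(vals))
        }
        M[i, j] <- best
      }
    }
  }
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || M[i, j] == 0L) next
    if (M[i, j] == M[i + 1L, j]) { stack[[length(stack) + 1L]] <- c(i + 1L, j); next }
    if (M[i, j] == M[i, j - 1L]) { stack[[length(stack) + 1L]] <- c(i, j - 1L); next }
    if (can_pair(ch[i], ch[j]) && j - i > min_loop &&
        M[i, j] == M[i + 1L, j - 1L] + 1L) {
      pairs <- rbind(pairs, c(i, j))
      stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
      next
    }
    for (k in (i + 1L):(j - 1L)) {
      if (M[i, k] + M[k + 1L, j] == M[i, j]) {
        stack[[length(stack) + 1L]] <- c(i, k)
        stack[[length(stack) + 1L]] <- c(k + 1L, j)
        break
      }
    }
  }
  list(pairs = pairs, n_pairs = if (n >= 2) M[1, n] else 0L)
}

pairs_to_dotbracket <- function(pairs, n) {
  db <- rep(".", n)
  if (nrow(pairs)) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}

#' Build a pair table from a dot-bracket string
#'
#' @param dot_bracket string over `(`, `.`, `)`.
#' @return integer vector; position of the partner (1-based) or NA if
#'   unpaired. Errors on unbalanced brackets.
#' @export
pair_table <- function(dot_bracket) {
  ch <- strsplit(dot_bracket, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c("(", ".", ")"))) {
    stop("dot-bracket contains characters other than '(', '.', ')'", call. = FALSE)
  }
  pt <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket: unmatched ')'", call. = FALSE)
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '('", call. = FALSE)
  pt
}

#' Fold a candidate sequence
#'
#' @param sequence DNA/RNA sequence (length >= 40 for candidate screening;
#'   shorter sequences are allowed for the builtin backend so it can be
#'   validated against exhaustive enumeration).
#' @param backend "builtin" (maximum-pairing DP, approximate energy) or
#'   "file" (pass-through of a supplied structure).
#' @param structure dot-bracket string (required for the "file" backend).
#' @param energy free energy in kcal/mol (required for the "file" backend).
#' @return list of class "mirexo_structure": sequence, dot_bracket, energy,
#'   pair_table, energy_approximate.
#' @export
fold <- function(sequence, backend = c("builtin", "file"), structure = NULL,
                 energy = NULL) {
  backend <- match.arg(backend)
  sequence <- toupper(chartr("U", "T", sequence))
  if (backend == "file") {
    if (is.null(structure) || is.null(energy)) {
      stop("file backend needs 'structure' and 'energy'", call. = FALSE)
    }
    if (nchar(structure) != nchar(sequence)) {
      stop("structure length differs from sequence length", call. = FALSE)
    }
    pt <- pair_table(structure)
    out <- list(sequence = sequence, dot_bracket = structure, energy = energy,
                pair_table = pt, energy_approximate = FALSE)
  } else {
    res <- nussinov_fold(sequence)
    db <- pairs_to_dotbracket(res$pairs, nchar(sequence))
    ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
    en <- if (nrow(res$pairs)) {
      sum(pair_energy(ch[res$pairs[, 1]], ch[res$pairs[, 2]]))
    } else 0
    out <- list(sequence = sequence, dot_bracket = db, energy = en,
                pair_table = pair_table(db), energy_approximate = TRUE)
  }
  class(out) <- "mirexo_structure"
  out
}

#' Decompose a structure into hairpin elements
#'
#' Requires a single-hairpin structure (exactly one terminal loop); returns
#' the hairpin span, terminal loop, stem base-pair count, and every interior
#' loop/bulge with per-side unpaired counts and positions.
#'
#' @param structure object from [fold()].
#' @return list of class "mirexo_hairpin": `ok` (logical), `reason` (when not
#'   ok), `span` (1-based inclusive c(start, end)), `terminal_loop` (1-based
#'   inclusive interval, length 0 encoded as NULL), `n_pairs`, `loops`
#'   (data.frame: left_count, right_count, positions as list-column).
#' @export
decompose <- function(structure) {
  db <- structure$dot_bracket
  pt <- structure$pair_table
  n_pairs <- sum(!is.na(pt)) / 2
  fail <- function(reason) {
    structure(list(ok = FALSE, reason = reason), class = "mirexo_hairpin")
  }
  if (n_pairs == 0) return(fail("no hairpin"))
  n_terminal <- length(gregexpr("\\(\\.*\\)", db)[[1]])
  if (gregexpr("\\(\\.*\\)", db)[[1]][1] == -1L) n_terminal <- 0L
  if (n_terminal != 1L) return(fail("not a single hairpin"))
  paired <- which(!is.na(pt))
  i <- min(paired); j <- pt[i]
  if (j != max(paired)) return(fail("not a single hairpin"))
  span <- c(i, j)
  loops <- list()
  repeat {
    nxt <- paired[paired > i & paired < j]
    if (!length(nxt)) {
      terminal <- if (j - i > 1) c(i + 1L, j - 1L) else NULL
      break
    }
    i2 <- min(nxt); j2 <- pt[i2]
    l <- i2 - i - 1L
    r <- j - j2 - 1L
    if (l > 0 || r > 0) {
      pos <- c(if (l > 0) (i + 1L):(i2 - 1L), if (r > 0) (j2 + 1L):(j - 1L))
      left_pos <- if (l > 0) (i + 1L):(i2 - 1L) else integer(0)
      right_pos <- if (r > 0) (j2 + 1L):(j - 1L) else integer(0)
      loops[[length(loops) + 1L]] <- list(left_count = l, right_count = r,
                                          left_pos = left_pos,
                                          right_pos = right_pos)
    }
    i <- i2; j <- j2
  }
  structure(list(ok = TRUE, span = span, terminal_loop = terminal,
                 n_pairs = n_pairs, loops = loops),
            class = "mirexo_hairpin")
}

CRITERIA_THRESHOLDS <- c(
  bulge_size = 12, stem_pairs = 16, energy = -15, hairpin_length = 50,
  loop_length = 20, mature_bulge = 8, mature_asymmetry = 4,
  mature_onesided_bulges = 2, mature_errors = 7, mature_paired = 12,
  mature_in_stem = 0.80)

#' Evaluate the eleven hairpin acceptance criteria
#'
#' Criteria (observed vs threshold): (1) every interior loop/bulge total
#' <= 12 nt; (2) stem base pairs >= 16; (3) free energy <= -15 kcal/mol;
#' (4) hairpin span >= 50 nt; (5) terminal loop <= 20 nt; (6) largest
#' single one-sided-bulge contribution to the mature region <= 8 nt; (7)
#' side asymmetry of two-sided interior loops touching the mature region
#' <= 4 (one-sided bulges are counted by criterion 8 instead); (8)
#' one-sided bulges overlapping the mature region <= 2; (9) mature
#' positions inside mismatch-type (two-sided) loops <= 7; (10) paired
#' mature positions >= 12; (11) fraction of mature positions inside the stem
#' (within the hairpin span, outside the terminal loop) >= 0.80.
#'
#' @param structure object from [fold()].
#' @param decomposition object from [decompose()]; must have `ok = TRUE`.
#' @param mature_start,mature_end 0-based half-open mature interval within
#'   the window.
#' @return data.frame of class "mirexo_criteria": criterion (1..11), name,
#'   observed, threshold, pass; attribute `accept` = all pass; attribute
#'   `energy_approximate` carried from the structure.
#' @export
evaluate_criteria <- function(structure, decomposition, mature_start,
                              mature_end) {
  if (!isTRUE(decomposition$ok)) {
    stop("cannot evaluate criteria: ", decomposition$reason, call. = FALSE)
  }
  n <- nchar(structure$sequence)
  if (mature_start < 0 || mature_end > n || mature_start >= mature_end) {
    stop("mature interval outside window", call. = FALSE)
  }
  mature <- (mature_start + 1L):mature_end   # 1-based positions
  pt <- structure$pair_table
  loops <- decomposition$loops
  span <- decomposition$span
  tl <- decomposition$terminal_loop
  tl_len <- if (is.null(tl)) 0L else tl[2] - tl[1] + 1L
  loop_tot <- vapply(loops, function(lp) lp$left_count + lp$right_count, numeric(1))
  obs1 <- if (length(loop_tot)) max(loop_tot) else 0
  in_mature <- function(pos) pos[pos %in% mature]
  m_contrib <- vapply(loops, function(lp) {
    length(in_mature(c(lp$left_pos, lp$right_pos)))
  }, numeric(1))
  overlapping <- if (length(loops)) m_contrib > 0 else logical(0)
  # "bulges" are one-sided loops, "errors" are mismatch-type (two-sided)
  # loops: criterion 6 bounds the largest single bulge inside the mature,
  # criterion 9 the total mismatch positions there, criterion 7 the side
  # asymmetry of two-sided loops, criterion 8 the bulge count
  asym <- vapply(loops, function(lp) abs(lp$left_count - lp$right_count), numeric(1))
  twosided <- vapply(loops, function(lp) {
    lp$left_count > 0 && lp$right_count > 0
  }, logical(1))
  onesided <- vapply(loops, function(lp) {
    xor(lp$left_count == 0, lp$right_count == 0)
  }, logical(1))
  obs6 <- if (any(overlapping & onesided)) max(m_contrib[overlapping & onesided]) else 0
  obs7 <- if (any(overlapping & twosided)) max(asym[overlapping & twosided]) else 0
  obs8 <- sum(onesided & overlapping)
  unpaired_m <- sum(m_contrib[twosided])
  paired_m <- sum(!is.na(pt[mature]))
  in_stem <- mature >= span[1] & mature <= span[2]
  if (!is.null(tl)) in_stem <- in_stem & !(mature >= tl[1] & mature <= tl[2])
  obs11 <- mean(in_stem)
  observed <- c(obs1, decomposition$n_pairs, structure$energy,
                span[2] - span[1] + 1L, tl_len, obs6, obs7, obs8,
                unpaired_m, paired_m, obs11)
  dir_ge <- c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
              TRUE, TRUE)
  thr <- unname(CRITERIA_THRESHOLDS)
  pass <- ifelse(dir_ge, observed >= thr, observed <= thr)
  rep <- data.frame(criterion = 1:11, name = names(CRITERIA_THRESHOLDS),
                    observed = observed, threshold = thr, pass = pass,
                    stringsAsFactors = FALSE)
  attr(rep, "accept") <- all(pass)
  attr(rep, "energy_approximate") <- isTRUE(structure$energy_approximate)
  class(rep) <- c("mirexo_criteria", class(rep))
  rep
}

#' Screen candidate windows for novel miRNA hairpins
#'
#' Each candidate tag carries one or two windows (from
#' [extract_hairpin_windows()]). A tag is accepted iff at least one window
#' folds into a single hairpin passing all eleven criteria; the passing
#' window with the lowest energy is reported.
#'
#' @param windows data.frame with columns tag, window, sequence,
#'   mature_start, mature_end.
#' @param backend "builtin" or "file".
#' @param structures for the "file" backend: data.frame as
#'   [read_dotbracket()], matched to windows by sequence.
#' @return list with `accepted` (data.frame: tag, window, energy), `reports`
#'   (list keyed "tag/window" of criteria reports or reject reasons).
#' @export
screen_candidates <- function(windows, backend = c("builtin", "file"),
                              structures = NULL) {
  backend <- match.arg(backend)
  reports <- list()
  acc_rows <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    key <- paste0(w$tag, "/", w$window)
    st <- tryCatch({
      if (backend == "file") {
        hit <- which(structures$sequence == w$sequence)
        if (!length(hit)) stop("no supplied structure for window", call. = FALSE)
        fold(w$sequence, "file", structure = structures$structure[hit[1]],
             energy = structures$energy[hit[1]])
      } else {
        fold(w$sequence, "builtin")
      }
    }, error = function(e) e)
    if (inherits(st, "error")) {
      reports[[key]] <- list(accept = FALSE, reason = conditionMessage(st))
      next
    }
    dec <- decompose(st)
    if (!isTRUE(dec$ok)) {
      reports[[key]] <- list(accept = FALSE, reason = dec$reason)
      next
    }
    rep <- evaluate_criteria(st, dec, w$mature_start, w$mature_end)
    reports[[key]] <- rep
    if (isTRUE(attr(rep, "accept"))) {
      acc_rows[[length(acc_rows) + 1L]] <- data.frame(
        tag = w$tag, window = w$window, energy = st$energy,
        stringsAsFactors = FALSE)
    }
  }
  accepted <- if (length(acc_rows)) {
    df <- do.call(rbind, acc_rows)
    sp <- split(df, df$tag)
    out <- do.call(rbind, lapply(sp, function(d) d[which.min(d$energy), ]))
    rownames(out) <- NULL
    out
  } else {
    data.frame(tag = character(0), window = character(0), energy = numeric(0),
               stringsAsFactors = FALSE)
  }
  list(accepted = accepted, reports = reports)
}

#' Dinucleotide shuffle of a sequence
#'
#' Random permutation preserving dinucleotide composition (Euler-path
#' shuffle approximated by repeated edge swaps on the dinucleotide walk);
#' used to build negative controls for the hairpin screen.
#'
#' @param sequence input sequence.
#' @return shuffled sequence with identical dinucleotide counts (up to the
#'   approximation of the swap walk).
#' @export
dinucleotide_shuffle <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 4) return(sequence)
  # swap two interior letters only when both left and both right neighbours
  # agree; the four affected dinucleotides then swap as a multiset
  for (rep_i in seq_len(4L * n)) {
    idx <- sample(2:(n - 1), 2)
    a <- min(idx); b <- max(idx)
    if (b - a < 2L) next
    if (ch[a - 1] == ch[b - 1] && ch[a + 1] == ch[b + 1]) {
      tmp <- ch[a]; ch[a] <- ch[b]; ch[b] <- tmp
    }
  }
  paste(ch, collapse = "")
}
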