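#' Toy amino-acid-level V(D)J recombination model
#'
#' A deliberately small generative model of CDR3 junction formation: a V
#' segment contributes a germline amino-acid prefix, a J segment a suffix;
#' both ends are independently trimmed, and an insert of i.i.d. residues is
#' placed between them. No nucleotide layer and no D segment — the model
#' exists to generate realistic-looking repertoires and to give every
#' sequence a tractable generation probability, not to be biologically exact.
#'
#' @param v_segments Tibble/data frame with `name`, `frequency`, `prefix`.
#' @param j_segments Tibble/data frame with `name`, `frequency`, `suffix`.
#' @param insert_length_dist Probability vector over 0..L_max inserted
#'   residues.
#' @param insert_residue_dist Named probability vector over the 20 amino
#'   acids.
#' @param trim_dist Probability vector over 0..T_max residues trimmed from
#'   prefix and suffix independently.
#' @return A `recomb_model` list.
#' @export
recomb_model <- function(v_segments, j_segments, insert_length_dist,
                         insert_residue_dist, trim_dist) {
  v_segments <- as_tibble(v_segments)
  j_segments <- as_tibble(j_segments)
  v_segments$frequency <- v_segments$frequency / sum(v_segments$frequency)
  j_segments$frequency <- j_segments$frequency / sum(j_segments$frequency)
  for (p in list(insert_length_dist, insert_residue_dist, trim_dist)) {
    if (abs(sum(p) - 1) > 1e-12) abort("probability vectors must sum to 1")
    if (any(p < 0)) abort("probabilities must be non-negative")
  }
  if (is.null(names(insert_residue_dist))) names(insert_residue_dist) <- AA20
  structure(list(v_segments = v_segments, j_segments = j_segments,
                 insert_length_dist = insert_length_dist,
                 insert_residue_dist = insert_residue_dist,
                 trim_dist = trim_dist),
            class = "recomb_model")
}

#' Default toy beta-chain model
#'
#' Twelve V and eight J toy segments with frequencies loosely shaped like
#' human TRB usage (Zipf-ish, TRBV20-1 most frequent). Illustrative, not
#' biological truth.
#'
#' @return A `recomb_model`.
#' @export
toy_trb_model <- function() {
  v <- tibble(
    name = c("TRBV20-1", "TRBV19", "TRBV5-1", "TRBV6-5", "TRBV28", "TRBV7-9",
             "TRBV4-1", "TRBV9", "TRBV2", "TRBV12-3", "TRBV18", "TRBV30"),
    prefix = c("CSARD", "CASSI", "CASSL", "CASSY", "CASSF", "CASSP",
               "CASSQ", "CASSV", "CASSE", "CASSG", "CASSN", "CAWSV"),
    frequency = c(17, 12, 10, 9, 8, 8, 7, 7, 6, 6, 5, 5))
  j <- tibble(
    name = c("TRBJ2-1", "TRBJ2-7", "TRBJ1-1", "TRBJ2-3", "TRBJ1-2",
             "TRBJ2-5", "TRBJ1-5", "TRBJ2-2"),
    suffix = c("NEQFF", "YEQYF", "TEAFF", "DTQYF", "YGYTF",
               "QETQYF", "QPQHF", "GELFF"),
    frequency = c(18, 16, 13, 12, 11, 11, 10, 9))
  recomb_model(v, j,
               insert_length_dist = c(0.10, 0.18, 0.22, 0.20, 0.14, 0.09, 0.05, 0.02),
               insert_residue_dist = setNames(rep(1 / 20, 20), AA20),
               trim_dist = c(0.45, 0.30, 0.17, 0.08))
}

#' Default toy alpha-chain model
#'
#' Ten V (including the MAIT-defining TRAV1-2 and the TRAV13-2 used by the
#' CD1b/c candidate rule) and six J toy segments.
#'
#' @return A `recomb_model`.
#' @export
toy_tra_model <- function() {
  v <- tibble(
    name = c("TRAV1-2", "TRAV13-2", "TRAV8-3", "TRAV12-1", "TRAV19",
             "TRAV26-1", "TRAV3", "TRAV29/DV5", "TRAV8-4", "TRAV27"),
    prefix = c("CAVMD", "CAENR", "CAVGA", "CAVNG", "CALSE",
               "CIVRV", "CAVRD", "CAASE", "CAVSP", "CAGAG"),
    frequency = c(9, 8, 10, 9, 10, 12, 11, 8, 12, 11))
  j <- tibble(
    name = c("TRAJ33", "TRAJ20", "TRAJ12", "TRAJ17", "TRAJ45", "TRAJ40"),
    suffix = c("SNYQLIW", "NDYKLSF", "DSSYKLIF", "KAAGNKLTF", "SGGGADGLTF", "TSGTYKYIF"),
    frequency = c(14, 12, 12, 22, 20, 20))
  recomb_model(v, j,
               insert_length_dist = c(0.15, 0.25, 0.25, 0.18, 0.10, 0.07),
               insert_residue_dist = setNames(rep(1 / 20, 20), AA20),
               trim_dist = c(0.50, 0.30, 0.20))
}

#' Generate one junction from a recombination model
#'
#' Samples V and J by frequency, trims both germline ends, draws an insert
#' length and i.i.d. insert residues, and concatenates. Junctions shorter than
#' `min_len` are resampled (bounded retries). The probability of the sampled
#' path (product of every choice probability) is returned alongside.
#'
#' @param model A `recomb_model`.
#' @param min_len Minimum junction length (default 5).
#' @param max_retries Retry bound for short junctions (default 100).
#' @return A list: `v_name`, `j_name`, `cdr3_aa`, `path_probability`.
#' @export
generate_junction <- function(model, min_len = 5, max_retries = 100) {
  for (try in seq_len(max_retries)) {
    vi <- sample.int(nrow(model$v_segments), 1, prob = model$v_segments$frequency)
    ji <- sample.int(nrow(model$j_segments), 1, prob = model$j_segments$frequency)
    tv <- sample.int(length(model$trim_dist), 1, prob = model$trim_dist) - 1L
    tj <- sample.int(length(model$trim_dist), 1, prob = model$trim_dist) - 1L
    il <- sample.int(length(model$insert_length_dist), 1,
                     prob = model$insert_length_dist) - 1L
    prefix <- model$v_segments$prefix[vi]
    suffix <- model$j_segments$suffix[ji]
    if (tv >= nchar(prefix) || tj >= nchar(suffix)) next
    prefix <- substr(prefix, 1, nchar(prefix) - tv)
    suffix <- substr(suffix, tj + 1, nchar(suffix))
    p <- model$v_segments$frequency[vi] * model$j_segments$frequency[ji] *
      model$trim_dist[tv + 1] * model$trim_dist[tj + 1] *
      model$insert_length_dist[il + 1]
    ins <- ""
    if (il > 0) {
      res <- sample(AA20, il, replace = TRUE, prob = model$insert_residue_dist)
      p <- p * prod(model$insert_residue_dist[res])
      ins <- paste(res, collapse = "")
    }
    cdr3 <- paste0(prefix, ins, suffix)
    if (nchar(cdr3) >= min_len) {
      return(list(v_name = model$v_segments$name[vi],
                  j_name = model$j_segments$name[ji],
                  cdr3_aa = cdr3, path_probability = unname(p)))
    }
  }
  abort("could not generate a junction of sufficient length; check the model")
}

#' Monte-Carlo generation-probability estimate
#'
#' Fraction of `n_samples` model draws whose junction equals `cdr3_aa` (and,
#' if given, whose V segment is `v_name`), with the binomial standard error.
#'
#' @param model A `recomb_model`.
#' @param cdr3_aa Target junction.
#' @param v_name Optional V segment restriction.
#' @param n_samples Number of draws (>= 1e4 recommended).
#' @param seed Integer seed.
#' @return A list: `estimate`, `se`.
#' @export
estimate_pgen_mc <- function(model, cdr3_aa, v_name = NULL, n_samples = 1e4, seed) {
  if (!missing(seed)) withr::local_seed(as.integer(seed))
  hits <- 0L
  for (i in seq_len(n_samples)) {
    g <- generate_junction(model)
    if (g$cdr3_aa == cdr3_aa && (is.null(v_name) || g$v_name == v_name)) {
      hits <- hits + 1L
    }
  }
  p <- hits / n_samples
  list(estimate = p, se = sqrt(p * (1 - p) / n_samples))
}

#' Exact generation probability by path enumeration
#'
#' Sums the path probabilities of every (V, J, trim, insert) combination that
#' emits `cdr3_aa`: for each V/J/trim combination the insert is forced to be
#' the residual middle of the sequence, so enumeration is over V x J x trims
#' only. Errors when the enumeration space exceeds `max_paths`.
#'
#' @param model A `recomb_model`.
#' @param cdr3_aa Target junction (vectorized).
#' @param v_name Optional V segment restriction.
#' @param min_len Junctions below this length are unreachable (default 5,
#'   matching [generate_junction()]).
#' @param max_paths Enumeration-space cap (default 1e6).
#' @return Numeric vector of probabilities.
#' @export
exact_pgen_small <- function(model, cdr3_aa, v_name = NULL, min_len = 5,
                             max_paths = 1e6) {
  nT <- length(model$trim_dist)
  space <- nrow(model$v_segments) * nrow(model$j_segments) * nT * nT
  if (space > max_paths) {
    abort("enumeration space too large; use estimate_pgen_mc() instead")
  }
  Lmax_ins <- length(model$insert_length_dist) - 1L
  vapply(cdr3_aa, function(s) {
    L <- nchar(s)
    if (L < min_len) return(0)
    total <- 0
    vs <- model$v_segments
    if (!is.null(v_name)) vs <- vs[vs$name == v_name, , drop = FALSE]
    for (vi in seq_len(nrow(vs))) {
      for (tv in 0:(nT - 1L)) {
        pre <- vs$prefix[vi]
        if (tv >= nchar(pre)) next
        pre <- substr(pre, 1, nchar(pre) - tv)
        lp <- nchar(pre)
        if (lp > L || substr(s, 1, lp) != pre) next
        for (ji in seq_len(nrow(model$j_segments))) {
          for (tj in 0:(nT - 1L)) {
            suf <- model$j_segments$suffix[ji]
            if (tj >= nchar(suf)) next
            suf <- substr(suf, tj + 1, nchar(suf))
            ls <- nchar(suf)
            li <- L - lp - ls
            if (li < 0 || li > Lmax_ins) next
            if (substr(s, L - ls + 1, L) != suf) next
            p <- vs$frequency[vi] * model$j_segments$frequency[ji] *
              model$trim_dist[tv + 1] * model$trim_dist[tj + 1] *
              model$insert_length_dist[li + 1]
            if (li > 0) {
              res <- strsplit(substr(s, lp + 1, lp + li), "")[[1]]
              pr <- model$insert_residue_dist[res]
              if (anyNA(pr)) next
              p <- p * prod(pr)
            }
            total <- total + p
          }
        }
      }
    }
    unname(total)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Geometric-mean banding of generation probabilities
#'
#' Computes the geometric mean and the standard deviation of the log10
#' probabilities and flags each value lying within one SD of the geometric
#' mean (inclusive at the boundary).
#'
#' @param pgen_values Positive generation probabilities.
#' @return A list: `geometric_mean`, `log_sd`, and the logical `within_band`
#'   flags.
#' @export
pgen_band <- function(pgen_values) {
  if (any(pgen_values <= 0) || anyNA(pgen_values)) {
    abort("generation probabilities must be positive")
  }
  lg <- log10(pgen_values)
  mu <- mean(lg)
  s <- if (length(lg) > 1) sd(lg) else 0
  list(geometric_mean = 10^mu, log_sd = s,
       within_band = abs(lg - mu) <= s + 1e-12)
}
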