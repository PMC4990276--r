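#' Group-evening restart policy
#'
#' The simulators keep the two GC-content groups "relatively even" by
#' rejection sampling: a finished run whose group counts differ by more than
#' the policy threshold is discarded and the whole simulation restarts from a
#' new seed. `mode = "absolute"` bounds `|n1 - n2|` by `threshold` sequences;
#' `mode = "fractional"` bounds it by `threshold * (n1 + n2)`. A difference
#' exactly equal to the bound passes (only a strictly exceeded bound
#' restarts).
#'
#' `check_at` controls which snapshots are tested: `"final"` (default) tests
#' only the last snapshot, `"every"` tests every snapshot except snapshot 0
#' (snapshot 0 of the lineage simulator has every sequence in group 1, so a
#' check there can never pass), `"none"` disables checking.
#'
#' @param mode `"absolute"` or `"fractional"`.
#' @param threshold integer >= 1 sequences (absolute) or a fraction in (0, 1)
#'   of the total (fractional).
#' @param check_at `"final"`, `"every"` or `"none"`.
#' @param max_restarts maximum number of attempts before giving up.
#' @return An `evening_policy` object.
#' @examples
#' evening_policy("absolute", 20)
#' evening_policy("fractional", 0.05)
#' @export
evening_policy <- function(mode = c("absolute", "fractional"), threshold,
                           check_at = c("final", "every", "none"),
                           max_restarts = 1000L) {
  mode <- match.arg(mode)
  check_at <- match.arg(check_at)
  if (mode == "absolute") {
    if (!.is_count(threshold)) {
      abort("absolute threshold must be an integer >= 1")
    }
    threshold <- as.integer(threshold)
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        threshold <= 0 || threshold >= 1) {
      abort("fractional threshold must lie in (0, 1)")
    }
  }
  if (!.is_count(max_restarts)) abort("max_restarts must be an integer >= 1")
  structure(
    list(mode = mode, threshold = threshold, check_at = check_at,
         max_restarts = as.integer(max_restarts)),
    class = "evening_policy"
  )
}

#' @export
print.evening_policy <- function(x, ...) {
  cat(sprintf("<evening_policy> %s threshold %s, checked at %s, max %d restarts\n",
              x$mode, format(x$threshold), x$check_at, x$max_restarts))
  invisible(x)
}

#' Test a group-count pair against an evening policy
#'
#' @param count1,count2 non-negative group sizes.
#' @param policy an [evening_policy()].
#' @return `TRUE` when the pair satisfies the policy bound.
#' @examples
#' check_evening(60, 40, evening_policy("absolute", 20)) # difference 20 passes
#' @export
check_evening <- function(count1, count2, policy) {
  stopifnot(inherits(policy, "evening_policy"), count1 >= 0, count2 >= 0)
  d <- abs(count1 - count2)
  if (policy$mode == "absolute") d <= policy$threshold
  else d <= policy$threshold * (count1 + count2)
}

snapshot_group_counts <- function(records) {
  g <- assign_group(records$bases)
  c(n1 = sum(records$count[g == "group1"]),
    n2 = sum(records$count[g == "group2"]))
}

#' Build an ancestral sequence
#'
#' With `gc_exact` supplied the sequence has exactly `gc_exact * length` G/C
#' characters, with the G/C positions, and the base choice at every position,
#' uniform at random; otherwise every base is drawn i.i.d. uniform over
#' A, C, G, T. Uses the current R random number stream.
#'
#' @param length sequence length in bases.
#' @param gc_exact optional exact GC fraction; `gc_exact * length` must be a
#'   whole number.
#' @param id record identifier.
#' @return A one-row sequence tibble.
#' @export
make_ancestor <- function(length, gc_exact = NULL, id = "ancestor") {
  stopifnot(.is_count(length))
  if (is.null(gc_exact)) {
    bases <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                   collapse = "")
  } else {
    k <- gc_exact * length
    if (abs(k - round(k)) > 1e-9) {
      abort(sprintf("gc_exact * length = %g is not a whole number", k))
    }
    k <- as.integer(round(k))
    chars <- rep(NA_character_, length)
    gc_pos <- sample.int(length, k)
    chars[gc_pos] <- sample(c("G", "C"), k, replace = TRUE)
    chars[-gc_pos] <- sample(c("A", "T"), length - k, replace = TRUE)
    if (k == length) chars <- sample(c("G", "C"), length, replace = TRUE)
    if (k == 0L) chars <- sample(c("A", "T"), length, replace = TRUE)
    bases <- paste(chars, collapse = "")
  }
  seq_tbl(id = id, bases = bases, group = assign_group(bases))
}

#' Apply one random base substitution
#'
#' The position is uniform over all positions and the replacement base is
#' uniform over the three bases differing from the current one, so the output
#' differs from the input at exactly one position. The same position may be
#' hit again by later calls (reversions are allowed).
#'
#' @param bases one or more ACGT strings; each receives one substitution.
#' @return The mutated string(s).
#' @export
substitute_once <- function(bases) {
  check_bases(toupper(bases))
  bases <- toupper(bases)
  n <- length(bases)
  len <- nchar(bases)
  pos <- vapply(len, function(l) sample.int(l, 1L), integer(1))
  old <- substr(bases, pos, pos)
  # the 3 alternatives to each base, in fixed A<C<G<T order
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  pick <- sample.int(3L, n, replace = TRUE)
  new <- vapply(seq_len(n), function(i) alt[[old[i]]][pick[i]],
                character(1))
  substr(bases, pos, pos) <- new
  bases
}

checked_indices <- function(policy, n_snapshots) {
  switch(policy$check_at,
         final = n_snapshots,
         every = if (n_snapshots > 1) 2:n_snapshots else integer(),
         none = integer())
}

new_generation_set <- function(snapshots, ancestor, seed, restarts_used,
                               policy, kind) {
  structure(
    list(snapshots = snapshots, ancestor = ancestor, seed = seed,
         restarts_used = restarts_used, policy = policy, kind = kind),
    class = "generation_set"
  )
}

run_with_restarts <- function(policy, seed, build) {
  last_diff <- NA_real_
  for (r in 0:(policy$max_restarts - 1L)) {
    set.seed(seed + r)
    run <- build()
    idx <- checked_indices(policy, length(run$snapshots))
    ok <- TRUE
    for (i in idx) {
      cnt <- snapshot_group_counts(run$snapshots[[i]])
      if (!check_evening(cnt[["n1"]], cnt[["n2"]], policy)) {
        last_diff <- abs(cnt[["n1"]] - cnt[["n2"]])
        ok <- FALSE
        break
      }
    }
    if (ok) {
      run$restarts_used <- r
      return(run)
    }
  }
  abort(sprintf(
    "evening policy not satisfied after %d attempts (last group-count difference: %g)",
    policy$max_restarts, last_diff))
}

#' Simulate a mutating sequence lineage
#'
#' Snapshot 0 holds `n_seqs` identical copies of an ancestor with exactly 50%
#' GC content; each subsequent snapshot applies one random base substitution
#' (see [substitute_once()]) independently to every sequence, so every record
#' at snapshot m carries exactly m substitution events. Runs that violate the
#' evening policy restart from `seed + attempt` until one passes.
#'
#' @param n_seqs number of sequences (default 100).
#' @param length sequence length in bases (default 100).
#' @param iterations number of mutation iterations (default 15).
#' @param policy an [evening_policy()]; default: absolute threshold of 20
#'   sequences, checked at the final snapshot.
#' @param seed integer seed; attempt r uses `seed + r`.
#' @return A `generation_set`: list with `snapshots` (list of sequence
#'   tibbles, index 1 = iteration 0), `ancestor`, `seed`, `restarts_used`,
#'   `policy`, `kind`.
#' @examples
#' \donttest{
#' gs <- simulate_mutation_lineage(n_seqs = 20, iterations = 5, seed = 1)
#' tidy(gs)
#' }
#' @export
simulate_mutation_lineage <- function(n_seqs = 100L, length = 100L,
                                      iterations = 15L,
                                      policy = evening_policy("absolute", 20),
                                      seed = 1L) {
  stopifnot(.is_count(n_seqs), .is_count(length), .is_count(iterations))
  build <- function() {
    anc <- make_ancestor(length, gc_exact = 0.5, id = "m0_1")
    snaps <- vector("list", iterations + 1L)
    bases <- rep(anc$bases, n_seqs)
    snaps[[1]] <- seq_tbl(id = paste0("m0_", seq_len(n_seqs)), bases = bases,
                          group = assign_group(bases), events = 0L)
    for (m in seq_len(iterations)) {
      bases <- substitute_once(bases)
      snaps[[m + 1L]] <- seq_tbl(id = paste0("m", m, "_", seq_len(n_seqs)),
                                 bases = bases, group = assign_group(bases),
                                 events = m)
    }
    new_generation_set(snaps, anc, seed, 0L, policy, "lineage")
  }
  run_with_restarts(policy, seed, build)
}

#' Simulate mutate-and-duplicate population growth
#'
#' Starts from a single ancestor and, at each generation, replaces every
#' sequence by an unchanged copy plus a copy carrying one random base
#' substitution, so snapshot g holds exactly 2^g sequences. The `events`
#' counter increments only on the mutated copy. Evening-policy restart
#' semantics are as in [simulate_mutation_lineage()].
#'
#' @param length sequence length in bases (default 100).
#' @param generations number of doubling generations (default 15, i.e. 32768
#'   final sequences).
#' @param policy an [evening_policy()]; default: fractional threshold 5% of
#'   the total, checked at the final snapshot.
#' @param seed integer seed; attempt r uses `seed + r`.
#' @param ancestor_gc exact GC fraction of the ancestor (default 0.5, which
#'   keeps the evening constraint satisfiable; `NULL` for a fully random
#'   ancestor).
#' @return A `generation_set` (see [simulate_mutation_lineage()]).
#' @export
simulate_population_growth <- function(length = 100L, generations = 15L,
                                       policy = evening_policy("fractional",
                                                               0.05),
                                       seed = 1L, ancestor_gc = 0.5) {
  stopifnot(.is_count(length), .is_count(generations))
  build <- function() {
    anc <- make_ancestor(length, gc_exact = ancestor_gc, id = "g0_1")
    snaps <- vector("list", generations + 1L)
    bases <- anc$bases
    events <- 0L
    snaps[[1]] <- seq_tbl(id = "g0_1", bases = bases,
                          group = assign_group(bases), events = events)
    for (g in seq_len(generations)) {
      mutated <- substitute_once(bases)
      # child 2i-1 is the unchanged copy of parent i, child 2i the mutated one
      n <- length(bases) * 2L
      new_bases <- character(n)
      new_bases[seq(1L, n, by = 2L)] <- bases
      new_bases[seq(2L, n, by = 2L)] <- mutated
      new_events <- integer(n)
      new_events[seq(1L, n, by = 2L)] <- events
      new_events[seq(2L, n, by = 2L)] <- events + 1L
      bases <- new_bases
      events <- new_events
      snaps[[g + 1L]] <- seq_tbl(id = paste0("g", g, "_", seq_len(n)),
                                 bases = bases, group = assign_group(bases),
                                 events = events)
    }
    new_generation_set(snaps, anc, seed, 0L, policy, "growth")
  }
  run_with_restarts(policy, seed, build)
}

#' @export
print.generation_set <- function(x, ...) {
  sizes <- vapply(x$snapshots, nrow, integer(1))
  cat(sprintf("<generation_set> %s: %d snapshots (sizes %s%s), seed %d, %d restart(s)\n",
              x$kind, length(x$snapshots),
              paste(utils::head(sizes, 4), collapse = ", "),
              if (length(sizes) > 4) ", ..." else "",
              x$seed, x$restarts_used))
  invisible(x)
}

#' @export
tidy.generation_set <- function(x, ...) {
  purrr::map_dfr(seq_along(x$snapshots), function(i) {
    s <- x$snapshots[[i]]
    cnt <- snapshot_group_counts(s)
    tibble(snapshot = i - 1L, n_seqs = sum(s$count),
           n_group1 = unname(cnt[["n1"]]), n_group2 = unname(cnt[["n2"]]),
           group_diff = abs(unname(cnt[["n1"]]) - unname(cnt[["n2"]])))
  })
}

#' @export
glance.generation_set <- function(x, ...) {
  final <- x$snapshots[[length(x$snapshots)]]
  tibble(kind = x$kind, n_snapshots = length(x$snapshots),
         n_final = sum(final$count), seed = x$seed,
         restarts_used = x$restarts_used,
         policy_mode = x$policy$mode, policy_threshold = x$policy$threshold,
         policy_check_at = x$policy$check_at)
}

#' Write a generation set to FASTA files plus a run manifest
#'
#' One FASTA file per snapshot, named `<prefix>_<index>.fasta` (index =
#' iteration/generation number), and `<prefix>_manifest.txt` recording the
#' seed, policy, restarts used and per-snapshot group counts.
#'
#' @param gs a `generation_set`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return The manifest path, invisibly.
#' @export
write_generation_set <- function(gs, dir, prefix = gs$kind) {
  stopifnot(inherits(gs, "generation_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(gs$snapshots)) {
    write_fasta(gs$snapshots[[i]],
                file.path(dir, sprintf("%s_%d.fasta", prefix, i - 1L)))
  }
  counts <- tidy(gs)
  manifest <- file.path(dir, paste0(prefix, "_manifest.txt"))
  lines <- c(
    sprintf("kind\t%s", gs$kind),
    sprintf("seed\t%d", gs$seed),
    sprintf("restarts_used\t%d", gs$restarts_used),
    sprintf("policy\t%s %s check_at=%s", gs$policy$mode,
            format(gs$policy$threshold), gs$policy$check_at),
    "snapshot\tn_seqs\tn_group1\tn_group2",
    sprintf("%d\t%d\t%d\t%d", counts$snapshot, counts$n_seqs,
            counts$n_group1, counts$n_group2)
  )
  writeLines(lines, manifest)
  invisible(manifest)
}

#' Exact size of the theoretical endpoint cluster distribution
#'
#' Unbounded substitution eventually reaches every possible sequence, so the
#' limiting number of unique sequences of length `n` over `b` bases is
#' exactly `b^n`. The value is computed with exact integer arithmetic
#' (schoolbook long multiplication) and returned as a decimal digit string,
#' since `b^n` overflows doubles for modest `n`.
#'
#' @param b number of possible base choices (>= 2).
#' @param n number of bases per sequence (>= 1).
#' @return The exact value of `b^n` as a character string of decimal digits.
#' @examples
#' endpoint_count(4, 2) # "16"
#' @export
endpoint_count <- function(b, n) {
  if (!.is_count(b, min = 2L)) abort("b must be an integer >= 2")
  if (!.is_count(n)) abort("n must be an integer >= 1")
  # digits little-endian in base 1e4; multiplier b may be large, so split it
  # into base-1e4 limbs as well
  base <- 10000L
  to_limbs <- function(x) {
    limbs <- integer(0)
    while (x > 0) {
      limbs <- c(limbs, as.integer(x %% base))
      x <- x %/% base
    }
    if (length(limbs) == 0) limbs <- 0L
    limbs
  }
  mul <- function(x, y) {
    out <- numeric(length(x) + length(y))
    for (i in seq_along(x)) {
      out[i:(i + length(y) - 1L)] <- out[i:(i + length(y) - 1L)] +
        x[i] * y
    }
    carry <- 0
    for (k in seq_along(out)) {
      v <- out[k] + carry
      out[k] <- v %% base
      carry <- floor(v / base)
    }
    while (carry > 0) {
      out <- c(out, carry %% base)
      carry <- floor(carry / base)
    }
    while (length(out) > 1 && out[length(out)] == 0) {
      out <- out[-length(out)]
    }
    out
  }
  acc <- 1
  bl <- to_limbs(b)
  acc <- to_limbs(1)
  for (i in seq_len(n)) acc <- mul(acc, bl)
  digits <- paste0(sprintf("%04d", rev(acc)), collapse = "")
  sub("^0+(?=.)", "", digits, perl = TRUE)
}
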