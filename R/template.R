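#' Parameters for the synthetic template pedigree
#'
#' The defaults emulate the profile of a deep founder-population pedigree:
#' 13 generations (counting the founder generation), ~4,998 members in one
#' connected pedigree with consanguineous (cousin-marriage) loops, 798
#' genotyped members sampled from the last three generations, 106 of them
#' affected in family clusters.
#'
#' @param n_generations total number of generations, founders included.
#' @param n_founder_couples founder couples in generation 1.
#' @param offspring_mean,offspring_dispersion mean and negative-binomial
#'   dispersion (`size`) of per-couple child counts.
#' @param consanguinity_rate probability that a marrying member takes a mate
#'   from inside the pedigree (non-sib, kinship <= 1/8) rather than a new
#'   married-in founder.
#' @param target_members target total size (achieved within about 10%).
#' @param n_genotyped members flagged genotyped (sampled from the last three
#'   generations).
#' @param n_affected genotyped members labelled affected (clustered in
#'   sibships so that affected individuals tend to have genotyped siblings).
#' @param n_unaffected genotyped members labelled unaffected; the remaining
#'   genotyped members keep unknown phenotype.
#' @param seed RNG seed; the same seed yields a byte-identical pedigree.
#' @return a list of class `"template_params"`.
#' @export
template_params <- function(n_generations = 13, n_founder_couples = 10,
                            offspring_mean = 3, offspring_dispersion = 4,
                            consanguinity_rate = 0.15, target_members = 4998,
                            n_genotyped = 798, n_affected = 106,
                            n_unaffected = 620, seed = 20130503) {
  p <- list(n_generations = n_generations,
            n_founder_couples = n_founder_couples,
            offspring_mean = offspring_mean,
            offspring_dispersion = offspring_dispersion,
            consanguinity_rate = consanguinity_rate,
            target_members = target_members,
            n_genotyped = n_genotyped, n_affected = n_affected,
            n_unaffected = n_unaffected, seed = seed)
  if (p$n_affected + p$n_unaffected > p$n_genotyped ||
      p$n_genotyped > p$target_members)
    ped_stop("infeasible_params",
             "need n_affected + n_unaffected <= n_genotyped <= target_members")
  if (p$consanguinity_rate < 0 || p$consanguinity_rate > 1)
    ped_stop("infeasible_params", "consanguinity_rate must be in [0, 1]")
  if (p$n_generations < 2 || p$n_founder_couples < 1)
    ped_stop("infeasible_params", "need >= 2 generations and >= 1 founder couple")
  structure(p, class = "template_params")
}

# planned generation sizes: geometric growth scaled to the member target
planned_generation_sizes <- function(p) {
  G <- p$n_generations
  s0 <- 2 * p$n_founder_couples
  if (G == 2) return(c(s0, max(p$target_members - s0, 1)))
  f <- function(r) s0 * sum(r^(0:(G - 1))) - p$target_members
  if (f(1e-3) > 0)
    ped_stop("infeasible_params",
             "target_members %d is below the founder generation size %d",
             p$target_members, s0)
  r <- uniroot(f, c(1e-3, 50))$root
  s0 * r^(0:(G - 1))
}

#' Generate a synthetic template pedigree
#'
#' Grows the pedigree generation by generation: couples draw
#' negative-binomial child numbers (rescaled so each generation hits its
#' planned size); children either marry a newly created founder spouse or,
#' with probability `consanguinity_rate`, a non-sib pedigree member of the
#' same generation with kinship at most 1/8 (preferring actual relatives,
#' which creates cousin-marriage loops).  Genotyped members are then sampled
#' from the last three generations and affection labels assigned in sibship
#' clusters.  The affection pattern is a fixed template label set, not
#' model-generated: it carries the sampling frame that simulated replicates
#' inherit.
#'
#' @param params a [template_params()].
#' @return a validated [pedigree()].
#' @export
generate_template <- function(params = template_params()) {
  stopifnot(inherits(params, "template_params"))
  with_seed(params$seed, generate_template_impl(params))
}

# sample() without the length-1 surprise
sample_vec <- function(x, size = length(x)) x[sample.int(length(x), size)]

generate_template_impl <- function(p) {
  G <- p$n_generations
  sizes <- planned_generation_sizes(p)
  mu <- p$offspring_mean
  cr <- p$consanguinity_rate

  # growing member table (creation order: parents precede children)
  father <- mother <- integer(0)  # indices, 0 = founder
  sex <- gen <- integer(0)
  add_member <- function(fa, mo, sx, g) {
    father[length(father) + 1L] <<- fa
    mother[length(mother) + 1L] <<- mo
    sex[length(sex) + 1L] <<- sx
    gen[length(gen) + 1L] <<- g
    length(father)
  }
  for (i in seq_len(p$n_founder_couples)) {
    add_member(0L, 0L, 1L, 0L)
    add_member(0L, 0L, 2L, 0L)
  }
  couples <- lapply(seq_len(p$n_founder_couples),
                    function(i) c(2L * i - 1L, 2L * i))

  for (g in 0:(G - 2)) {
    n_couples <- length(couples)
    if (!n_couples) break
    k_next <- if (g + 2 <= G - 1) max(1L, ceiling(sizes[g + 3] / mu)) else 0L
    n_children <- max(round(sizes[g + 2] - k_next * (1 - cr)),
                      ceiling(k_next * (1 + cr)), 1)
    counts <- rnbinom(n_couples, mu = mu, size = p$offspring_dispersion)
    diff <- n_children - sum(counts)
    if (diff > 0) {
      counts <- counts + tabulate(sample.int(n_couples, diff, replace = TRUE),
                                  n_couples)
    } else if (diff < 0) {
      k <- -diff
      while (k > 0) {
        pos <- which(counts > 0)
        take <- sample_vec(pos, min(k, length(pos)))
        counts[take] <- counts[take] - 1L
        k <- k - length(take)
      }
    }
    children <- integer(0)
    for (ci in seq_len(n_couples)) {
      cp <- couples[[ci]]
      kk <- counts[ci]
      if (kk > 0) {
        sx <- rbinom(kk, 1L, 0.5) + 1L
        for (j in seq_len(kk))
          children <- c(children, add_member(cp[1], cp[2], sx[j], g + 1L))
      }
    }
    # marriages for the next breeding generation
    couples <- list()
    if (k_next > 0L && length(children)) {
      phi <- .kinship_tabular(father, mother)  # creation order is topological
      parent_key <- paste(father[children], mother[children])
      unmarried <- rep(TRUE, length(children))
      pool <- sample_vec(children)
      for (k in seq_len(k_next)) {
        left <- which(unmarried[match(pool, children)])
        if (!length(left)) break
        a <- pool[left[1]]
        ai <- match(a, children)
        unmarried[ai] <- FALSE
        b <- NA_integer_
        if (runif(1) < cr) {
          cand <- which(unmarried & sex[children] != sex[a] &
                        parent_key != parent_key[ai] &
                        phi[children, a] <= 0.125 + 1e-12)
          if (length(cand)) {
            related <- cand[phi[children[cand], a] > 1e-12]
            pick <- if (length(related)) related else cand
            b <- children[sample_vec(pick, 1)]
            unmarried[match(b, children)] <- FALSE
          }
        }
        if (is.na(b)) b <- add_member(0L, 0L, if (sex[a] == 1L) 2L else 1L, g + 1L)
        couples[[length(couples) + 1L]] <-
          if (sex[a] == 1L) c(a, b) else c(b, a)
      }
    }
  }

  # trim overshoot from the (childless) last generation
  n <- length(father)
  if (n > p$target_members) {
    last <- which(gen == G - 1L)
    is_parent <- seq_len(n) %in% c(father, mother)
    removable <- last[!is_parent[last]]
    drop <- sample_vec(removable, min(length(removable), n - p$target_members))
    keep <- setdiff(seq_len(n), drop)
    remap <- integer(n); remap[keep] <- seq_along(keep)
    father <- c(0L, remap)[father[keep] + 1L]
    mother <- c(0L, remap)[mother[keep] + 1L]
    sex <- sex[keep]; gen <- gen[keep]
    n <- length(keep)
  }

  last3 <- which(gen >= max(0L, G - 3L))
  if (length(last3) < p$n_genotyped)
    ped_stop("infeasible_params",
             "only %d members in the last 3 generations; cannot flag %d genotyped",
             length(last3), p$n_genotyped)
  genotyped_idx <- sort(sample_vec(last3, p$n_genotyped))

  # affected labels clustered by sibship among the genotyped
  key <- paste(father[genotyped_idx], mother[genotyped_idx], genotyped_idx * (father[genotyped_idx] == 0L))
  sibships <- split(genotyped_idx, key)
  affected <- integer(0)
  for (s in sibships[sample.int(length(sibships))]) {
    if (length(affected) >= p$n_affected) break
    hit <- s[runif(length(s)) < 0.7]
    affected <- c(affected, hit)
  }
  if (length(affected) > p$n_affected)
    affected <- affected[seq_len(p$n_affected)]
  while (length(affected) < p$n_affected) {
    extra <- sample_vec(setdiff(genotyped_idx, affected), 1)
    affected <- c(affected, extra)
  }
  rest <- setdiff(genotyped_idx, affected)
  unaffected <- if (length(rest) > p$n_unaffected)
    sample_vec(rest, p$n_unaffected) else rest

  aff <- rep(0L, n)
  aff[affected] <- 2L
  aff[unaffected] <- 1L
  ids <- sprintf("I%05d", seq_len(n))
  fa_id <- rep(NA_character_, n); fa_id[father > 0L] <- ids[father[father > 0L]]
  mo_id <- rep(NA_character_, n); mo_id[mother > 0L] <- ids[mother[mother > 0L]]
  pedigree(id = ids,
           father = fa_id,
           mother = mo_id,
           sex = sex, affection = aff,
           genotyped = seq_len(n) %in% genotyped_idx,
           phenotyped = aff != 0L)
}
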