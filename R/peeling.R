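# ---- generic discrete factor algebra over pedigree members ----------------
# A factor is list(vars = sorted integer member indices, vals = numeric
# vector of length ns^|vars|, column-major with the FIRST var fastest).

factor_new <- function(vars, vals) list(vars = vars, vals = vals)

# expand a factor's values onto the cell grid of a superset of variables
factor_expand <- function(f, vars_out, ns) {
  N <- ns^length(vars_out)
  if (!length(f$vars)) return(rep(f$vals, N))
  idx <- numeric(N)
  cells <- seq_len(N) - 1
  for (q in seq_along(f$vars)) {
    p <- match(f$vars[q], vars_out)
    coord <- (cells %/% ns^(p - 1)) %% ns
    idx <- idx + coord * ns^(q - 1)
  }
  f$vals[idx + 1]
}

factor_product <- function(fs, ns) {
  vars_out <- sort(unique(unlist(lapply(fs, `[[`, "vars"))))
  vals <- factor_expand(fs[[1]], vars_out, ns)
  for (f in fs[-1]) vals <- vals * factor_expand(f, vars_out, ns)
  factor_new(vars_out, vals)
}

factor_marginalize <- function(f, v, ns) {
  k <- length(f$vars)
  p <- match(v, f$vars)
  arr <- array(f$vals, rep(ns, k))
  if (k == 1L) return(factor_new(integer(0), sum(arr)))
  arr <- aperm(arr, c(setdiff(seq_len(k), p), p))
  dim(arr) <- c(ns^(k - 1), ns)
  factor_new(f$vars[-p], rowSums(arr))
}

# greedy min-degree elimination order on the factor interaction graph
elimination_order <- function(factors, n_vars) {
  adj <- vector("list", n_vars)
  for (f in factors) for (v in f$vars)
    adj[[v]] <- unique(c(adj[[v]], setdiff(f$vars, v)))
  remaining <- sort(unique(unlist(lapply(factors, `[[`, "vars"))))
  order <- integer(0)
  while (length(remaining)) {
    deg <- vapply(remaining, function(v) length(intersect(adj[[v]], remaining)), 1L)
    v <- remaining[which.min(deg)]  # ties: smallest index (which.min)
    nb <- intersect(adj[[v]], remaining)
    for (w in nb) adj[[w]] <- unique(c(adj[[w]], setdiff(nb, w)))
    order <- c(order, v)
    remaining <- setdiff(remaining, v)
  }
  order
}

# variable elimination; returns natural-log likelihood (-Inf for an exact
# zero, i.e. data inconsistent with the model -- rescaling at every step
# rules out numerical underflow)
ve_likelihood <- function(factors, ns, max_states = 1e8) {
  order <- elimination_order(factors, max(unlist(lapply(factors, `[[`, "vars"))))
  logscale <- 0
  active <- factors
  for (v in order) {
    has <- vapply(active, function(f) v %in% f$vars, TRUE)
    group <- active[has]
    active <- active[!has]
    vars_u <- sort(unique(unlist(lapply(group, `[[`, "vars"))))
    if (ns^length(vars_u) > max_states)
      ped_stop("elimination_too_wide",
               "elimination clique of %d members exceeds the state budget",
               length(vars_u))
    f <- factor_marginalize(factor_product(group, ns), v, ns)
    m <- max(f$vals)
    if (m == 0) return(-Inf)
    f$vals <- f$vals / m
    logscale <- logscale + log(m)
    active[[length(active) + 1L]] <- f
  }
  logscale + sum(log(vapply(active, function(f) f$vals[1], 1)))
}

# ---- two-locus (trait x marker) pedigree likelihood ------------------------
# haplotype coding h in 0..3 = 2*d + m  (d = disease allele, m = marker
# allele "2"); ordered genotype state = 4*h_pat + h_mat in 0..15.

hap_d <- function(h) h %/% 2L
hap_m <- function(h) h %% 2L

transmission_gamete <- function(theta) {
  # T[gamete + 1, parent_state + 1]
  T <- matrix(0, 4, 16)
  for (s in 0:15) {
    h1 <- s %/% 4L; h2 <- s %% 4L
    for (g in 0:3) {
      pr <- 0.5 * (hap_d(g) == hap_d(h1)) *
        ((1 - theta) * (hap_m(g) == hap_m(h1)) + theta * (hap_m(g) == hap_m(h2))) +
        0.5 * (hap_d(g) == hap_d(h2)) *
        ((1 - theta) * (hap_m(g) == hap_m(h2)) + theta * (hap_m(g) == hap_m(h1)))
      T[g + 1, s + 1] <- pr
    }
  }
  T
}

#' Parametric linkage model
#'
#' Trait model for two-point parametric linkage: disease allele frequency
#' and penetrances by number of disease-allele copies.  The defaults follow
#' the affecteds-only convention: rare disease allele (1%), near-zero
#' penetrance so unaffected phenotypes carry no information, dominant
#' `(0, 1e-4, 1e-4)` or recessive `(0, 0, 1e-4)`.
#'
#' @param mode `"dominant"` or `"recessive"`.
#' @param q disease allele frequency.
#' @param penetrance penetrance by 0/1/2 disease-allele copies; default per
#'   mode as above.
#' @param affecteds_only if `TRUE`, unaffected individuals are treated as
#'   unknown (their phenotype contributes no likelihood factor).
#' @return an object of class `"linkage_model"`.
#' @export
linkage_model <- function(mode = c("dominant", "recessive"), q = 0.01,
                          penetrance = NULL, affecteds_only = TRUE) {
  mode <- match.arg(mode)
  if (is.null(penetrance))
    penetrance <- if (mode == "dominant") c(0, 1e-4, 1e-4) else c(0, 0, 1e-4)
  stopifnot(all(penetrance >= 0 & penetrance <= 1), q > 0, q < 1)
  structure(list(mode = mode, q = q, penetrance = penetrance,
                 affecteds_only = affecteds_only),
            class = "linkage_model")
}

# structural factors + evidence builders for one subpedigree; everything
# that does not depend on the observed marker data is computed once
twopoint_engine <- function(sub, model, marker_freq, theta = 0) {
  topo <- ped_topology(sub)
  n <- length(topo$ids)
  pd <- model$q; pm <- marker_freq
  # joint two-locus factors
  php <- c((1 - pd) * (1 - pm), (1 - pd) * pm, pd * (1 - pm), pd * pm)
  st <- 0:15
  prior16 <- php[st %/% 4L + 1] * php[st %% 4L + 1]
  Tg <- transmission_gamete(theta)
  trans16 <- numeric(16^3)  # vars (c, f, m) with c fastest
  cs <- 0:15
  gp <- cs %/% 4L; gm <- cs %% 4L
  for (mstate in 0:15) for (fstate in 0:15) {
    pr <- Tg[gp + 1, fstate + 1] * Tg[gm + 1, mstate + 1]
    trans16[(mstate * 16 + fstate) * 16 + cs + 1] <- pr
  }
  nD16 <- hap_d(st %/% 4L) + hap_d(st %% 4L)
  nM16 <- hap_m(st %/% 4L) + hap_m(st %% 4L)
  # single-locus factors (ns = 4), allele a in {0,1}; state = 2*pat + mat
  single <- function(p) {
    ph <- c(1 - p, p)
    s4 <- 0:3
    prior4 <- ph[s4 %/% 2L + 1] * ph[s4 %% 2L + 1]
    T4 <- matrix(0, 2, 4)
    for (s in s4) for (g in 0:1)
      T4[g + 1, s + 1] <- 0.5 * ((g == s %/% 2L) + (g == s %% 2L))
    trans4 <- numeric(4^3)
    cg <- s4
    for (ms in s4) for (fs in s4) {
      pr <- T4[cg %/% 2L + 1, fs + 1] * T4[cg %% 2L + 1, ms + 1]
      trans4[(ms * 4 + fs) * 4 + cg + 1] <- pr
    }
    list(prior = prior4, trans = trans4, n_alleles = s4 %/% 2L + s4 %% 2L)
  }
  pen_vec <- function(nD) { # penetrance evidence by affection code
    f <- model$penetrance
    list(`2` = f[nD + 1],
         `1` = if (model$affecteds_only) rep(1, length(nD)) else 1 - f[nD + 1],
         `0` = rep(1, length(nD)))
  }
  structural <- function(trans, prior, ns) {
    fs <- list()
    for (i in seq_len(n)) {
      if (topo$father[i] == 0L) {
        fs[[length(fs) + 1L]] <- factor_new(i, prior)
      } else {
        vars <- c(i, topo$father[i], topo$mother[i])
        ord <- order(vars)
        arr <- array(trans, rep(ns, 3))
        fs[[length(fs) + 1L]] <- factor_new(vars[ord],
                                            as.vector(aperm(arr, ord)))
      }
    }
    fs
  }
  s4t <- single(pd); s4m <- single(pm)
  list(topo = topo, n = n,
       joint = structural(trans16, prior16, 16),
       trait4 = structural(s4t$trans, s4t$prior, 4),
       marker4 = structural(s4m$trans, s4m$prior, 4),
       pen16 = pen_vec(nD16), pen4 = pen_vec(s4t$n_alleles),
       nM16 = nM16, nM4 = s4m$n_alleles)
}

engine_loglik <- function(eng, which = c("joint", "trait", "marker"),
                          affection, dosage) {
  which <- match.arg(which)
  ns <- if (which == "joint") 16L else 4L
  fs <- switch(which, joint = eng$joint, trait = eng$trait4,
               marker = eng$marker4)
  aff <- affection[eng$topo$ids]
  aff[is.na(aff)] <- 0L
  for (i in seq_len(eng$n)) {
    ev <- rep(1, ns)
    if (which != "marker") {
      pen <- if (ns == 16L) eng$pen16 else eng$pen4
      ev <- ev * pen[[as.character(aff[i])]]
    }
    if (which != "trait") {
      d <- dosage[eng$topo$ids[i]]
      if (!is.na(d)) {
        nm <- if (ns == 16L) eng$nM16 else eng$nM4
        ev <- ev * (nm == d)
      }
    }
    if (any(ev != 1)) fs[[length(fs) + 1L]] <- factor_new(i, ev)
  }
  ve_likelihood(fs, ns)
}

#' Exact two-locus pedigree likelihood
#'
#' Joint likelihood of observed marker genotypes and affection status under
#' a trait-marker two-locus model: founder two-locus genotypes at population
#' frequencies (Hardy-Weinberg and linkage equilibrium), transmission with
#' recombination fraction `theta`, marker penetrance = observation
#' indicator, trait penetrance from the [linkage_model()].  Computed exactly
#' (consanguineous loops included) by variable elimination over a
#' min-degree order, with per-step rescaling so an exact zero (Mendelian
#' inconsistency) is distinguishable from underflow.
#'
#' @param sub a [pedigree()] (typically a subpedigree).
#' @param marker_dosage named vector of observed marker dosages (count of
#'   allele "2"; `NA` = untyped).
#' @param marker_freq frequency of marker allele "2".
#' @param model a [linkage_model()].
#' @param theta trait-marker recombination fraction in `[0, 0.5]`.
#' @param affection optional named affection vector overriding `sub$affection`.
#' @return log10 likelihood (`-Inf` for Mendelian-inconsistent data).
#' @export
pedigree_likelihood <- function(sub, marker_dosage, marker_freq, model,
                                theta, affection = NULL) {
  stopifnot(theta >= 0, theta <= 0.5)
  if (is.null(affection)) affection <- setNames(sub$affection, sub$id)
  eng <- twopoint_engine(sub, model, marker_freq, theta)
  engine_loglik(eng, "joint", affection, marker_dosage) / log(10)
}

#' Heterogeneity LOD
#'
#' `HLOD(alpha) = sum_i log10(alpha * 10^{Z_i} + 1 - alpha)` maximized over
#' the admixture proportion `alpha` on a 0.01 grid followed by one
#' golden-section refinement.  `alpha = 1` recovers the total LOD, so
#' `HLOD >= max(0, LOD)`.
#'
#' @param z per-subpedigree log10 likelihood ratios.
#' @return list with `hlod` and `alpha`.
#' @export
hlod <- function(z) {
  z <- z[is.finite(z) | z < 0]
  if (!length(z)) return(list(hlod = 0, alpha = 0))
  obj <- function(a) sum(log10(a * 10^z + 1 - a))
  grid <- seq(0, 1, by = 0.01)
  vals <- vapply(grid, obj, 1)
  best <- which.max(vals)
  lo <- grid[max(1, best - 1)]; hi <- grid[min(length(grid), best + 1)]
  opt <- optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-9)
  if (opt$objective >= vals[best])
    list(hlod = opt$objective, alpha = opt$maximum)
  else list(hlod = vals[best], alpha = grid[best])
}

#' Two-point LOD and HLOD at one marker
#'
#' Scores the trait model at the marker: per subpedigree
#' `Z_i = log10 L_i(theta = 0) - log10 L_i(theta = 1/2)`, with the
#' unlinked likelihood factorizing exactly into trait-only times
#' marker-only likelihoods; `LOD = sum Z_i` and the admixture HLOD from
#' [hlod()].
#'
#' @param set a [split_pedigree()] result (or any list of pedigrees in
#'   `$subpedigrees`).
#' @param rep a replicate (list with `genotypes` and `affection`).
#' @param marker marker name or column index into `rep$genotypes`.
#' @param model a [linkage_model()].
#' @param marker_freq frequency of marker allele "2" (simulation truth by
#'   default).
#' @param engines optional cached engine list from [twopoint_engines()].
#' @return list of class `"linkage_result"`: `marker`, `Z`, `LOD`, `HLOD`,
#'   `alpha_hat`.
#' @export
twopoint_lod <- function(set, rep, marker, model, marker_freq = 0.2,
                         engines = NULL) {
  if (is.null(engines))
    engines <- twopoint_engines(set, model, marker_freq,
                                affection = rep$affection)
  dos <- rep$genotypes[, marker]
  names(dos) <- rownames(rep$genotypes)
  z <- vapply(engines, function(eng) {
    lj <- engine_loglik(eng$joint0, "joint", rep$affection, dos)
    lm <- engine_loglik(eng$joint0, "marker", rep$affection, dos)
    (lj - eng$ltrait - lm) / log(10)
  }, 1)
  h <- hlod(z)
  structure(list(marker = if (is.character(marker)) marker else
                   colnames(rep$genotypes)[marker],
                 Z = z, LOD = sum(z), HLOD = h$hlod, alpha_hat = h$alpha),
            class = "linkage_result")
}

#' Precompute per-subpedigree peeling structures
#'
#' The transmission/prior factors, elimination structure and the trait-only
#' likelihood depend only on the subpedigree, model and allele frequency,
#' so they are computed once and reused across markers and replicates that
#' share the affection pattern.  The trait-only log-likelihood is
#' recomputed per call when affection differs (see [twopoint_scan()]).
#'
#' @inheritParams twopoint_lod
#' @param affection affection vector used for the cached trait-only
#'   likelihood (default: the subpedigrees' own labels).
#' @return list of engines, one per subpedigree.
#' @export
twopoint_engines <- function(set, model, marker_freq = 0.2, affection = NULL) {
  lapply(set$subpedigrees, function(sub) {
    aff <- if (is.null(affection)) setNames(sub$affection, sub$id) else affection
    eng <- twopoint_engine(sub, model, marker_freq, theta = 0)
    list(joint0 = eng,
         ltrait = engine_loglik(eng, "trait", aff, NULL))
  })
}

#' Two-point scan over all markers of a replicate
#'
#' @inheritParams twopoint_lod
#' @param markers marker columns to scan (default: all).
#' @return data.frame with `marker`, `LOD`, `HLOD`, `alpha_hat`.
#' @export
twopoint_scan <- function(set, rep, model, marker_freq = 0.2, markers = NULL) {
  if (is.null(markers)) markers <- seq_len(ncol(rep$genotypes))
  observed <- rownames(rep$genotypes)[!is.na(rep$genotypes[, 1])]
  Z <- matrix(0, length(set$subpedigrees), length(markers))
  for (s in seq_along(set$subpedigrees)) {
    sub <- set$subpedigrees[[s]]
    eng <- twopoint_engine(sub, model, marker_freq, theta = 0)
    ltrait <- engine_loglik(eng, "trait", rep$affection, NULL)
    cm <- compile_marker_scan(eng, rep$affection, observed)
    for (j in seq_along(markers)) {
      dos <- rep$genotypes[, markers[j]]
      names(dos) <- rownames(rep$genotypes)
      Z[s, j] <- compiled_z(cm, dos, ltrait)
    }
  }
  rows <- lapply(seq_along(markers), function(j) {
    h <- hlod(Z[, j])
    data.frame(marker = colnames(rep$genotypes)[markers[j]] %||%
                 as.character(markers[j]),
               LOD = sum(Z[, j]), HLOD = h$hlod, alpha_hat = h$alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("Two-point %s: LOD %.3f, HLOD %.3f (alpha %.2f) over %d subpedigrees\n",
              x$marker, x$LOD, x$HLOD, x$alpha_hat, length(x$Z)))
  invisible(x)
}

# ---- compiled elimination schedules ---------------------------------------
# The elimination structure (order, cliques, expansion index maps) depends
# only on which members carry evidence, not on the evidence values, so for
# marker scans it is compiled once per subpedigree and each marker costs
# only indexed products and row sums.

compile_schedule <- function(factors, ns, max_states = 1e8) {
  ord <- elimination_order(factors, max(unlist(lapply(factors, `[[`, "vars"))))
  avail <- lapply(factors, `[[`, "vars")
  alive <- rep(TRUE, length(avail))
  steps <- list()
  for (v in ord) {
    slots <- which(alive & vapply(avail, function(vs) v %in% vs, TRUE))
    vars_u <- sort(unique(unlist(avail[slots])))
    rest <- setdiff(vars_u, v)
    enum_vars <- c(rest, v)  # eliminated var is the slowest dimension
    N <- ns^length(enum_vars)
    if (N > max_states)
      ped_stop("elimination_too_wide",
               "elimination clique of %d members exceeds the state budget",
               length(enum_vars))
    cells <- seq_len(N) - 1
    maps <- lapply(slots, function(s) {
      fv <- avail[[s]]
      idx <- numeric(N)
      for (q in seq_along(fv)) {
        p <- match(fv[q], enum_vars)
        idx <- idx + ((cells %/% ns^(p - 1)) %% ns) * ns^(q - 1)
      }
      as.integer(idx + 1)
    })
    alive[slots] <- FALSE
    avail[[length(avail) + 1L]] <- rest
    alive[length(avail)] <- TRUE
    steps[[length(steps) + 1L]] <- list(slots = slots, maps = maps, N = N,
                                        out_len = as.integer(N / ns),
                                        out_slot = length(avail))
  }
  list(steps = steps, n_slots = length(avail),
       final = which(alive & lengths(avail) == 0))
}

evaluate_schedule <- function(sched, vals, ns) {
  logscale <- 0
  for (st in sched$steps) {
    prod <- vals[[st$slots[1]]][st$maps[[1]]]
    if (length(st$slots) > 1)
      for (k in 2:length(st$slots))
        prod <- prod * vals[[st$slots[k]]][st$maps[[k]]]
    out <- if (st$out_len == 1L) sum(prod)
           else rowSums(matrix(prod, st$out_len, ns))
    m <- max(out)
    if (m == 0) return(-Inf)
    logscale <- logscale + log(m)
    vals[[st$out_slot]] <- out / m
  }
  for (s in sched$final) logscale <- logscale + log(vals[[s]])
  logscale
}

# compile joint (16-state) and marker-only (4-state) scan machinery for one
# subpedigree: evidence slots are members with a phenotype or an observed
# marker genotype (the observation pattern is constant across markers)
compile_marker_scan <- function(eng, affection, observed_ids) {
  aff <- affection[eng$topo$ids]
  aff[is.na(aff)] <- 0L
  obs <- eng$topo$ids %in% observed_ids
  compile_one <- function(fs, ns, use_pen) {
    ev_members <- which((use_pen & aff != 0L) | obs)
    slots <- length(fs)
    ev_slot <- integer(eng$n)
    for (i in ev_members) {
      slots <- slots + 1L
      fs[[slots]] <- factor_new(i, rep(1, ns))
      ev_slot[i] <- slots
    }
    list(sched = compile_schedule(fs, ns),
         base_vals = lapply(fs, `[[`, "vals"),
         ev_slot = ev_slot, ev_members = ev_members)
  }
  list(joint = compile_one(eng$joint, 16L, use_pen = TRUE),
       marker = compile_one(eng$marker4, 4L, use_pen = FALSE),
       aff = aff, obs = obs, eng = eng)
}

# per-marker Z for a compiled subpedigree: dosage named by id (NA = untyped)
compiled_z <- function(cm, dosage, ltrait) {
  eng <- cm$eng
  dos <- dosage[eng$topo$ids]
  run <- function(part, ns, use_pen) {
    vals <- part$base_vals
    for (i in part$ev_members) {
      ev <- rep(1, ns)
      if (use_pen && cm$aff[i] != 0L)
        ev <- ev * (if (ns == 16L) eng$pen16 else eng$pen4)[[as.character(cm$aff[i])]]
      if (!is.na(dos[i]))
        ev <- ev * ((if (ns == 16L) eng$nM16 else eng$nM4) == dos[i])
      vals[[part$ev_slot[i]]] <- ev
    }
    evaluate_schedule(part$sched, vals, ns)
  }
  lj <- run(cm$joint, 16L, TRUE)
  lm <- run(cm$marker, 4L, FALSE)
  (lj - ltrait - lm) / log(10)
}
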