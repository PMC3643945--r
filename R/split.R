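#' Subjects of interest for pedigree splitting
#'
#' Affected individuals plus unaffected full siblings of affected
#' individuals (members labelled unaffected sharing both parents with an
#' affected member).  Members of unknown phenotype are never subjects.
#'
#' @param ped a [pedigree()].
#' @return character vector of ids (possibly empty).
#' @export
subjects_of_interest <- function(ped) {
  key <- paste(ped$father, ped$mother)
  affected <- ped$affection == 2L
  aff_keys <- unique(key[affected & !is.na(ped$father)])
  sibs <- ped$affection == 1L & !is.na(ped$father) & key %in% aff_keys
  sort(ped$id[affected | sibs])
}

# --- internal machinery on integer member indices ---------------------------

split_context <- function(ped) {
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  n <- nrow(ped)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(fi[i])) {
      adj[[i]] <- c(adj[[i]], fi[i], mi[i])
      adj[[fi[i]]] <- c(adj[[fi[i]]], i)
      adj[[mi[i]]] <- c(adj[[mi[i]]], i)
    }
  }
  # NA-free parent indices: founders point at the phantom slot n + 1
  fi1 <- ifelse(is.na(fi), n + 1L, fi)
  mi1 <- ifelse(is.na(mi), n + 1L, mi)
  list(ped = ped, fi = fi, mi = mi, fi1 = fi1, mi1 = mi1,
       hasp = !is.na(fi), n = n, adj = adj)
}

# multi-source BFS; returns integer distances (NA = unreachable) and
# predecessor pointers for path extraction
ped_bfs <- function(ctx, sources) {
  dist <- rep(NA_integer_, ctx$n)
  pred <- rep(NA_integer_, ctx$n)
  dist[sources] <- 0L
  frontier <- sources
  d <- 0L
  while (length(frontier)) {
    nxt <- unlist(ctx$adj[frontier], use.names = FALSE)
    src <- rep.int(frontier, lengths(ctx$adj[frontier]))
    new <- is.na(dist[nxt]) & !duplicated(nxt)
    nxt <- nxt[new]; src <- src[new]
    d <- d + 1L
    dist[nxt] <- d
    pred[nxt] <- src
    frontier <- nxt
  }
  list(dist = dist, pred = pred)
}

# close a member set: whenever a member has exactly one parent inside the
# set, pull in the other parent (the mate needed for a valid transmission)
close_member_set <- function(ctx, set) {
  inset <- logical(ctx$n + 1L)
  inset[set] <- TRUE
  active <- seq_len(ctx$n)
  repeat {
    hf <- inset[active] & ctx$hasp[active] & inset[ctx$fi1[active]]
    hm <- inset[active] & ctx$hasp[active] & inset[ctx$mi1[active]]
    need <- active[hf != hm]
    if (!length(need)) break
    inset[ctx$fi1[need]] <- TRUE
    inset[ctx$mi1[need]] <- TRUE
  }
  which(inset[seq_len(ctx$n)])
}

set_bits <- function(ctx, set) {
  inset <- logical(ctx$n + 1L)
  inset[set] <- TRUE
  nf <- sum(inset[ctx$fi1[set]])  # phantom slot stays FALSE for founders
  2L * nf - (length(set) - nf)
}

# carve a standalone pedigree out of a member set: parents outside the set
# are stripped, making their children founders of the subpedigree
build_subpedigree <- function(ped, ids) {
  sub <- ped
  class(sub) <- "data.frame"
  sub <- sub[sub$id %in% ids, , drop = FALSE]
  sub$father[!(sub$father %in% sub$id)] <- NA_character_
  sub$mother[!(sub$mother %in% sub$id)] <- NA_character_
  # closure guarantees both-or-neither, but enforce anyway
  single <- xor(is.na(sub$father), is.na(sub$mother))
  sub$father[single] <- NA_character_
  sub$mother[single] <- NA_character_
  pedigree(sub$id, sub$father, sub$mother, sub$sex, sub$affection,
           sub$genotyped, sub$phenotyped)
}

#' Split a pedigree under a bit-size limit
#'
#' Divides a pedigree into subpedigrees covering all subjects of interest
#' while keeping every subpedigree's bit size within `bit_limit`, in the
#' spirit of sub-pedigree extraction tools for linkage: (1) subjects are
#' grouped into sibships and each sibship plus its parents seeds one
#' subpedigree; (2) pairs of subpedigrees are greedily merged through their
#' minimal connecting pedigree (shortest relationship path, plus the mates
#' required for transmission validity) as long as the merged bit size stays
#' within the limit, preferring merges that gain the most subjects per added
#' bit (ties: smaller merged bit size, then smallest member id); (3) maximal
#' un-mergeable subpedigrees are emitted.  Deterministic for fixed input.
#'
#' @param ped a [pedigree()].
#' @param subjects ids to cover (default [subjects_of_interest()]).
#' @param bit_limit maximum bit size per subpedigree (default 24).
#' @return an object of class `"subpedigree_set"`: list with `subpedigrees`
#'   (list of [pedigree()]), `membership` (list of id vectors),
#'   `assignment` (named integer: subject id -> subpedigree index) and
#'   `bit_limit`.
#' @export
split_pedigree <- function(ped, subjects = subjects_of_interest(ped),
                           bit_limit = 24L) {
  if (!length(subjects))
    ped_stop("no_subjects", "no subjects of interest to cover")
  if (!all(subjects %in% ped$id))
    ped_stop("id_not_found", "subject id(s) not in pedigree")
  ctx <- split_context(ped)

  if (bit_size(ped) <= bit_limit) {
    return(structure(list(subpedigrees = list(ped),
                          membership = list(ped$id),
                          assignment = setNames(rep(1L, length(subjects)),
                                                sort(subjects)),
                          bit_limit = as.integer(bit_limit)),
                     class = "subpedigree_set"))
  }

  sidx <- match(sort(subjects), ped$id)
  skey <- ifelse(is.na(ctx$fi[sidx]), paste0("F", sidx),
                 paste(ctx$fi[sidx], ctx$mi[sidx]))
  sib_groups <- split(sidx, skey)
  comps <- lapply(sib_groups, function(s) {
    seed <- close_member_set(ctx, unique(c(s, ctx$fi[s], ctx$mi[s])[
      !is.na(c(s, ctx$fi[s], ctx$mi[s]))]))
    bits <- set_bits(ctx, seed)
    if (bits > bit_limit)
      ped_stop("sibship_too_large",
               "sibship {%s} plus parents has bit size %d > limit %d",
               paste(ped$id[s], collapse = ", "), bits, bit_limit)
    list(members = seed, subjects = s, bits = bits,
         bfs = ped_bfs(ctx, seed))
  })
  names(comps) <- NULL

  merged_set <- function(a, b) {
    # shortest connection from component a to component b, if any
    d <- comps[[a]]$bfs$dist[comps[[b]]$members]
    if (all(is.na(d))) return(NULL)
    tgt <- comps[[b]]$members[which.min(d)]
    path <- integer(0)
    v <- tgt
    while (!is.na(v)) {
      path <- c(path, v)
      v <- comps[[a]]$bfs$pred[v]
    }
    close_member_set(ctx, unique(c(comps[[a]]$members, comps[[b]]$members, path)))
  }
  eval_pair <- function(a, b) {
    ms <- merged_set(a, b)
    if (is.null(ms)) return(NULL)
    bits <- set_bits(ctx, ms)
    if (bits > bit_limit) return(NULL)
    added <- bits - max(comps[[a]]$bits, comps[[b]]$bits)
    list(set = ms, bits = bits,
         score = (length(comps[[a]]$subjects) + length(comps[[b]]$subjects)) /
           (1 + max(0L, added)))
  }

  alive <- rep(TRUE, length(comps))
  cache <- new.env(parent = emptyenv())
  pair_key <- function(a, b) paste0(min(a, b), ":", max(a, b))
  get_pair <- function(a, b) {
    k <- pair_key(a, b)
    if (is.null(cache[[k]])) cache[[k]] <- list(eval_pair(min(a, b), max(a, b)))
    cache[[k]][[1]]
  }
  repeat {
    idx <- which(alive)
    best <- NULL; best_ab <- NULL
    for (i in seq_along(idx)) for (j in seq_len(i - 1L)) {
      a <- idx[j]; b <- idx[i]
      pr <- get_pair(a, b)
      if (is.null(pr)) next
      better <- is.null(best) ||
        pr$score > best$score + 1e-12 ||
        (abs(pr$score - best$score) <= 1e-12 &&
           (pr$bits < best$bits ||
              (pr$bits == best$bits &&
                 min(ped$id[pr$set]) < min(ped$id[best$set]))))
      if (better) { best <- pr; best_ab <- c(a, b) }
    }
    if (is.null(best)) break
    a <- best_ab[1]; b <- best_ab[2]
    comps[[a]] <- list(members = best$set,
                       subjects = sort(unique(c(comps[[a]]$subjects,
                                                comps[[b]]$subjects))),
                       bits = best$bits,
                       bfs = ped_bfs(ctx, best$set))
    alive[b] <- FALSE
    for (k in which(alive)) if (k != a) {
      cache[[pair_key(a, k)]] <- NULL
      cache[[pair_key(b, k)]] <- NULL
    }
  }

  keep <- which(alive)
  # deterministic emission order: by smallest member id
  ordk <- order(vapply(keep, function(k) min(ped$id[comps[[k]]$members]), ""))
  keep <- keep[ordk]
  subpeds <- lapply(keep, function(k) build_subpedigree(ped, ped$id[comps[[k]]$members]))
  membership <- lapply(keep, function(k) sort(ped$id[comps[[k]]$members]))
  assignment <- integer(0)
  for (s in seq_along(keep)) {
    ids <- ped$id[comps[[keep[s]]]$subjects]
    assignment[ids] <- s
  }
  structure(list(subpedigrees = subpeds, membership = membership,
                 assignment = assignment[sort(names(assignment))],
                 bit_limit = as.integer(bit_limit)),
            class = "subpedigree_set")
}

#' @export
print.subpedigree_set <- function(x, ...) {
  bits <- vapply(x$subpedigrees, bit_size, 1L)
  cat(sprintf("Subpedigree set: %d subpedigrees (bit limit %d), sizes %s, bits %s\n",
              length(x$subpedigrees), x$bit_limit,
              paste(vapply(x$subpedigrees, nrow, 1L), collapse = "/"),
              paste(bits, collapse = "/")))
  invisible(x)
}

#' Kinship within each subpedigree
#'
#' Recomputes kinship treating each subpedigree's parentless members as
#' founders, i.e. from the sub-pedigree structures rather than the whole
#' pedigree.
#'
#' @param set a [split_pedigree()] result.
#' @return list of [kinship()] matrices, one per subpedigree.
#' @export
subpedigree_kinship <- function(set) lapply(set$subpedigrees, kinship)

# every individual appearing in any subpedigree, used exactly once:
# subjects go to their assigned subpedigree, others to the first (smallest
# index) subpedigree containing them
subpedigree_member_assignment <- function(set) {
  out <- set$assignment
  for (s in seq_along(set$membership)) {
    new <- setdiff(set$membership[[s]], names(out))
    out[new] <- s
  }
  out[order(names(out))]
}

#' Block-diagonal kinship over a subpedigree set
#'
#' For association analyses on split pedigrees: each member is used exactly
#' once (subjects in their assigned subpedigree, connectors in the first
#' subpedigree containing them), kinship is recomputed within subpedigree
#' structures, and members of different subpedigrees are treated as
#' unrelated (no cross-subpedigree entries).
#'
#' @param set a [split_pedigree()] result.
#' @return a `"kinship_matrix"` over the union of subpedigree members.
#' @export
subpedigree_kinship_union <- function(set) {
  assign <- subpedigree_member_assignment(set)
  kms <- subpedigree_kinship(set)
  ids <- names(assign)
  phi <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (s in seq_along(kms)) {
    block <- ids[assign == s]
    phi[block, block] <- kms[[s]]$phi[block, block]
  }
  structure(list(ids = ids, phi = phi, h = 2 * diag(phi) - 1),
            class = "kinship_matrix")
}
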