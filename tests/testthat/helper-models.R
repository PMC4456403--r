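# Shared model snippets and independent oracles.

phospho_with_inits <- function(n = 30L) {
  paste(fixture("intro_phospho")$source, sprintf("
| init Raf{x~u, y~u} %d | init MEK{t~u, S218~u, S222~u} %d", n, n))
}

death_model <- function(n0 = 40L, k = 0.25) {
  sprintf("agent A = new {};\nA -> {%s}|\ninit A %d", k, n0)
}

# Independent well-typedness checker (not the backend's): unique site names
# per agent, every link label exactly twice per agent list, ground inits.
assert_well_typed <- function(k) {
  side_ok <- function(agents) {
    labs <- integer()
    for (a in agents) {
      nms <- vapply(a$sites, function(s) s$name, "")
      if (anyDuplicated(nms) > 0L) return(FALSE)
      for (s in a$sites) if (s$link$kind == "label") labs <- c(labs, s$link$k)
    }
    all(table(labs) == 2L)
  }
  for (r in k$rules) {
    if (!side_ok(r$lhs) || !side_ok(r$rhs)) return(FALSE)
  }
  for (ini in k$inits) {
    if (!side_ok(ini$agents)) return(FALSE)
    for (a in ini$agents) {
      for (s in a$sites) {
        if (s$name == "comp") next
        if (is.na(s$internal)) return(FALSE)
        if (!s$link$kind %in% c("free", "label")) return(FALSE)
      }
    }
  }
  TRUE
}

# Brute-force embedding oracle: enumerate every injective assignment of
# pattern agents to live mixture agents and check all constraints directly.
# Independent of the backtracking matcher.
oracle_embeddings <- function(pattern, mix) {
  live <- which(!vapply(mix$agents, is.null, TRUE))
  np <- length(pattern)
  if (np == 0L || length(live) < np) return(0L)
  perms <- function(v, k) {
    if (k == 0L) return(list(integer()))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i], k - 1L)) {
        out[[length(out) + 1L]] <- c(v[[i]], rest)
      }
    }
    out
  }
  ok_assignment <- function(phi) {
    ends <- list()
    for (i in seq_len(np)) {
      a <- mix$agents[[phi[[i]]]]
      pa <- pattern[[i]]
      if (!identical(pa$name, a$name)) return(FALSE)
      for (s in pa$sites) {
        if (!s$name %in% names(a$internal)) return(FALSE)
        if (!is.na(s$internal) &&
            !identical(a$internal[[s$name]], s$internal)) return(FALSE)
        bonded <- !is.null(a$partner[[s$name]])
        res <- switch(s$link$kind,
          free = !bonded, bound = bonded, any = TRUE,
          label = {
            if (!bonded) return(FALSE)
            key <- as.character(s$link$k)
            ends[[key]] <- c(ends[[key]],
                             list(list(idx = i, site = s$name)))
            TRUE
          })
        if (!res) return(FALSE)
      }
    }
    for (key in names(ends)) {
      e <- ends[[key]]
      if (length(e) != 2L) return(FALSE)
      p1 <- mix$agents[[phi[[e[[1L]]$idx]]]]$partner[[e[[1L]]$site]]
      if (as.integer(p1[[1L]]) != phi[[e[[2L]]$idx]] ||
          !identical(p1[[2L]], e[[2L]]$site)) return(FALSE)
    }
    TRUE
  }
  sum(vapply(perms(live, np), ok_assignment, TRUE))
}

# Mixture builder from init text appended to agent definitions.
mixture_from <- function(defs, init_text) {
  kappa_mixture(lbsk_compile(paste(defs, init_text, sep = "\n")))
}
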