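# The concrete Kappa semantics: site-expression primitives (typing, default,
# update, seal), link-label encoding, linearisation of site assignments, the
# translation of normal-form agent values to Kappa agents (with the
# compartment-encoding `comp` site), well-typedness, and program composition.

lbsk_kappa_error <- function(msg) {
  stop(errorCondition(paste0("kappa backend error: ", msg),
                      class = c("lbsk_kappa_error", "lbsk_error")))
}

#' Default site expression for a site type
#'
#' An unmentioned site constrains nothing: wildcard internal state, link
#' either free or bound.  Independent of the declared value set.
#'
#' @param type Character vector of allowed internal state values.
#' @return A site expression `list(internal, link)`.
#' @export
default_site <- function(type) {
  list(internal = int_wildcard(), link = link_any())
}

#' Update one site expression with another
#'
#' Componentwise: the identity leaves the component untouched, anything else
#' overwrites it.
#'
#' @param old,new Site expressions (`list(internal, link)`).
#' @export
update_site <- function(old, new) {
  list(
    internal = if (new$internal$kind == "identity") old$internal else new$internal,
    link = if (new$link$kind == "identity") old$link else new$link
  )
}

#' Type-check a site expression against a site type
#'
#' True iff the internal values used by the expression are declared by the
#' type; wildcard and identity internals use none.
#'
#' @param es Site expression.
#' @param type Character vector of allowed internal state values.
#' @export
typecheck_site <- function(es, type) {
  if (es$internal$kind == "value") es$internal$v %in% type else TRUE
}

#' Seal a site expression into a namespace
#'
#' Prepends the bit-string `b` to the namespace of a link label; all other
#' site expressions are returned unchanged.  Sealing confines the link
#' labels of a module body so they cannot capture labels carried by actual
#' parameters.
#'
#' @param es Site expression.
#' @param b Bit-string (character).
#' @export
seal_site <- function(es, b) {
  if (es$link$kind == "label") {
    es$link$ns <- paste0(b, es$link$ns)
  }
  es
}

# --- printable agent names ---------------------------------------------------

# A `new` agent prints under its declared name when that is unique among all
# `new` definitions; colliding declarations print under their defining
# identifier, with a numeric suffix as a last resort.
printable_names <- function(registry) {
  uids <- names(registry)
  declared <- vapply(registry, function(r) r$name, "")
  defids <- vapply(registry, function(r) r$defid, "")
  out <- setNames(character(length(uids)), uids)
  for (nm in unique(declared)) {
    grp <- uids[declared == nm]
    if (length(grp) == 1L) {
      out[[grp]] <- nm
    } else {
      for (uid in grp) out[[uid]] <- defids[[uid]]
    }
  }
  # resolve residual collisions with a numeric suffix
  while (anyDuplicated(out)) {
    dup <- out[duplicated(out)][[1L]]
    grp <- names(out)[out == dup]
    for (i in seq_along(grp)) {
      if (i > 1L) out[[grp[[i]]]] <- paste0(dup, "_", i)
    }
  }
  out
}

path_token <- function(path) {
  if (length(path) == 0L) "top" else paste(path, collapse = ".")
}

# --- linearisation and agent translation ------------------------------------

# Sites of a normal-form agent are a finite map; Kappa agents are lists.
# Linearise in lexicographic byte order of site names, dropping sites that
# constrain nothing (wildcard internal, free-or-bound link): in Kappa an
# unmentioned site means exactly that.  Identity variants must not survive
# to this level.
kap_sites <- function(sites) {
  if (length(sites) == 0L) return(list())
  nms <- sort(names(sites), method = "radix")
  out <- list()
  for (nm in nms) {
    s <- sites[[nm]]
    if (s$internal$kind == "identity" || s$link$kind == "identity") {
      lbsk_kappa_error(sprintf(
        "identity site expression leaked to the Kappa level on site '%s'", nm))
    }
    if (s$internal$kind == "wildcard" && s$link$kind == "any") next
    internal <- if (s$internal$kind == "value") s$internal$v else NA_character_
    out[[length(out) + 1L]] <- list(name = nm, internal = internal,
                                    link = s$link)
  }
  out
}

# Translate one normal-form agent value (a complex) to a list of Kappa
# agents; the compartment path is encoded as a last, distinguished site
# `comp` whose internal state is the dot-joined path ("top" when empty).
kap_value <- function(value, name_map) {
  lapply(value, function(p) {
    sites <- kap_sites(p$sites)
    sites[[length(sites) + 1L]] <- list(name = "comp",
                                        internal = path_token(p$path),
                                        link = link_free())
    list(name = name_map[[p$uid]], sites = sites)
  })
}

# --- link encoding -----------------------------------------------------------

# Distinct (label, namespace) pairs are renumbered to consecutive positive
# integers in first-occurrence order.  Kappa labels are rule-scoped, so a
# per-rule encoding is observably equivalent to a global injective one.
enc_links <- function(agents) {
  seen <- character()
  relabel <- function(agents) {
    lapply(agents, function(a) {
      a$sites <- lapply(a$sites, function(s) {
        if (s$link$kind == "label") {
          key <- paste0(s$link$k, "@", s$link$ns)
          if (!key %in% seen) seen <<- c(seen, key)
          s$link <- list(kind = "label", k = match(key, seen))
        }
        s
      })
      a
    })
  }
  relabel(agents)
}

enc_rule_links <- function(lhs, rhs) {
  both <- enc_links(c(lhs, rhs))
  list(lhs = both[seq_along(lhs)],
       rhs = both[length(lhs) + seq_along(rhs)])
}

# --- well-typedness ----------------------------------------------------------

check_agent_list <- function(agents, where) {
  labels <- integer()
  for (a in agents) {
    nms <- vapply(a$sites, function(s) s$name, "")
    if (anyDuplicated(nms)) {
      lbsk_kappa_error(sprintf("duplicate site in agent '%s' (%s)",
                               a$name, where))
    }
    for (s in a$sites) {
      if (s$link$kind == "label") labels <- c(labels, s$link$k)
    }
  }
  tab <- table(labels)
  bad <- names(tab)[tab != 2L]
  if (length(bad)) {
    lbsk_kappa_error(sprintf(
      "link label%s %s occur%s %s times on %s; each label must occur exactly twice",
      if (length(bad) > 1L) "s" else "", paste(bad, collapse = ", "),
      if (length(bad) > 1L) "" else "s",
      paste(tab[bad], collapse = ", "), where))
  }
  invisible(TRUE)
}

# Wildcards on the right hand side are admitted only where they preserve:
# a `?` or `!_` link on a product site is allowed iff the positionally
# matched reactant agent carries the same link kind on that site (a no-op in
# Kappa); a wildcard internal state on a matched agent means "unchanged",
# and on a created agent it is filled with the first declared value by the
# simulator.  Genuinely new link wildcards in products are rejected.
check_rhs_wildcards <- function(lhs, rhs, label) {
  for (j in seq_along(rhs)) {
    a <- rhs[[j]]
    matched <- if (j <= length(lhs) && identical(lhs[[j]]$name, a$name)) {
      lhs[[j]]
    } else {
      NULL
    }
    for (s in a$sites) {
      if (!s$link$kind %in% c("any", "bound")) next
      ok <- FALSE
      if (!is.null(matched)) {
        for (ls in matched$sites) {
          if (identical(ls$name, s$name) &&
              identical(ls$link$kind, s$link$kind)) {
            ok <- TRUE
            break
          }
        }
      }
      if (!ok) {
        lbsk_kappa_error(sprintf(
          "rule '%s': link wildcard on product site '%s.%s' does not preserve a matching reactant site",
          label, a$name, s$name))
      }
    }
  }
  invisible(TRUE)
}

rule_to_kappa <- function(rule, name_map) {
  lhs <- do.call(c, c(lapply(rule$lhs, kap_value, name_map = name_map),
                      list(list())))
  rhs <- do.call(c, c(lapply(rule$rhs, kap_value, name_map = name_map),
                      list(list())))
  enc <- enc_rule_links(lhs, rhs)
  check_agent_list(enc$lhs, sprintf("the LHS of rule '%s'", rule$label))
  check_agent_list(enc$rhs, sprintf("the RHS of rule '%s'", rule$label))
  check_rhs_wildcards(enc$lhs, enc$rhs, rule$label)
  list(label = rule$label, rate = rule$rate, lhs = enc$lhs, rhs = enc$rhs)
}

init_to_kappa <- function(init, name_map) {
  if (!is.numeric(init$count) || init$count < 1 ||
      init$count != floor(init$count)) {
    lbsk_kappa_error("initial copy numbers must be positive integers")
  }
  # groundness is checked before linearisation: every declared site must
  # carry a concrete internal state and a free link or a bond
  for (p in init$value) {
    for (nm in names(p$sites)) {
      s <- p$sites[[nm]]
      if (s$internal$kind != "value") {
        lbsk_kappa_error(sprintf(
          "initial condition is not ground: site '%s.%s' has a wildcard internal state",
          p$name, nm))
      }
      if (!s$link$kind %in% c("free", "label")) {
        lbsk_kappa_error(sprintf(
          "initial condition is not ground: site '%s.%s' has a wildcard link",
          p$name, nm))
      }
    }
  }
  agents <- enc_links(kap_value(init$value, name_map))
  check_agent_list(agents, "an initial condition")
  list(agents = agents, count = as.integer(init$count))
}

# --- programs ----------------------------------------------------------------

kappa_program <- function(rules, inits, signatures) {
  structure(list(rules = rules, inits = inits, signatures = signatures),
            class = "kappa_program")
}

#' @export
print.kappa_program <- function(x, ...) {
  cat(sprintf("<kappa program: %d rules, %d init complexes, %d agent kinds>\n",
              length(x$rules), length(x$inits), length(x$signatures)))
  invisible(x)
}

rule_key <- function(r) {
  paste(r$label, r$rate,
        paste(vapply(c(r$lhs, r$rhs), agent_string, ""), collapse = "|"))
}

#' Compose two compiled Kappa programs
#'
#' Rule-set union and init-list concatenation; the empty program is the
#' identity.
#'
#' @param k1,k2 Objects of class `kappa_program`.
#' @export
kappa_compose <- function(k1, k2) {
  rules <- c(k1$rules, k2$rules)
  rules <- rules[!duplicated(vapply(rules, rule_key, ""))]
  sigs <- k1$signatures
  for (nm in names(k2$signatures)) {
    if (is.null(sigs[[nm]])) {
      sigs[[nm]] <- k2$signatures[[nm]]
    } else {
      merged <- sigs[[nm]]
      for (s in names(k2$signatures[[nm]])) {
        merged[[s]] <- union(merged[[s]], k2$signatures[[nm]][[s]])
      }
      sigs[[nm]] <- merged
    }
  }
  kappa_program(rules, c(k1$inits, k2$inits), sigs)
}

#' The empty Kappa program
#' @export
kappa_nil <- function() kappa_program(list(), list(), list())
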