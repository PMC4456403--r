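# KaSim v3 dialect writer, the canonical flat renderer used for golden
# comparisons, and reversible-pair detection on compiled programs.

link_string <- function(link, kasim = FALSE) {
  switch(link$kind,
    free = "",
    bound = "!_",
    any = "?",
    label = paste0("!", link$k),
    lbsk_kappa_error("identity link in output")
  )
}

site_string <- function(s) {
  paste0(s$name,
         if (!is.na(s$internal)) paste0("~", s$internal) else "",
         link_string(s$link))
}

agent_string <- function(a, drop_top_comp = FALSE, braces = FALSE) {
  sites <- a$sites
  if (drop_top_comp) {
    sites <- Filter(function(s) !(s$name == "comp" && s$internal == "top"),
                    sites)
  }
  open <- if (braces) "{" else "("
  close <- if (braces) "}" else ")"
  paste0(a$name, open,
         paste(vapply(sites, site_string, ""), collapse = ", "), close)
}

#' Write a compiled program in the KaSim v3 dialect
#'
#' Emits `%agent:` signature lines (declared internal values plus the
#' compartment-encoding `comp` site), one rule line per rule
#' (`'label' LHS -> RHS @ rate`) and `%init:` lines.  Output ordering is
#' deterministic: signatures by agent name, rules by label, inits in list
#' order.
#'
#' @param k A `kappa_program` from [lbsk_compile()].
#' @param path Optional file to write to.
#' @return The text, invisibly when `path` is given.
#' @export
write_kasim <- function(k, path = NULL) {
  lines <- c("# flat Kappa (KaSim v3 dialect) generated by lbskappa", "")
  for (nm in sort(names(k$signatures) %||% character(), method = "radix")) {
    sig <- k$signatures[[nm]]
    sites <- vapply(names(sig), function(s) {
      paste0(s, paste0("~", sig[[s]], collapse = ""))
    }, "")
    lines <- c(lines, paste0("%agent: ", nm, "(",
                             paste(sites, collapse = ","), ")"))
  }
  rules <- k$rules[order(vapply(k$rules, function(r) r$label, ""),
                         method = "radix")]
  for (r in rules) {
    lines <- c(lines, paste0(
      "'", r$label, "' ",
      paste(vapply(r$lhs, agent_string, ""), collapse = ","),
      " -> ",
      paste(vapply(r$rhs, agent_string, ""), collapse = ","),
      " @ ", num_str(r$rate)))
  }
  for (ini in k$inits) {
    lines <- c(lines, paste0(
      "%init: ", ini$count, " ",
      paste(vapply(ini$agents, agent_string, ""), collapse = ",")))
  }
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

# --- canonical renderer ------------------------------------------------------

# Connected components of an agent list under its bonds, in first-agent
# order; members keep their original order.
split_complexes <- function(agents) {
  n <- length(agents)
  if (n == 0L) return(list())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  ends <- list() # label -> first endpoint agent index
  for (i in seq_len(n)) {
    for (s in agents[[i]]$sites) {
      if (s$link$kind == "label") {
        key <- as.character(s$link$k)
        if (is.null(ends[[key]])) {
          ends[[key]] <- i
        } else {
          ra <- find(ends[[key]])
          rb <- find(i)
          if (ra != rb) parent[[rb]] <- ra
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comps <- list()
  for (r in unique(roots)) {
    comps[[length(comps) + 1L]] <- which(roots == r)
  }
  comps
}

canon_side <- function(agents) {
  # renumber labels in first-occurrence order, then group into complexes
  relabelled <- enc_links(agents)
  comps <- split_complexes(relabelled)
  paste(vapply(comps, function(idx) {
    paste(vapply(relabelled[idx], agent_string, "",
                 drop_top_comp = TRUE, braces = TRUE), collapse = "-")
  }, ""), collapse = " + ")
}

#' Canonical flat rendering of a compiled program's rules
#'
#' Renders each rule in the flat curly-brace dialect with link labels
#' renumbered in first-occurrence order, complexes grouped with `-` and
#' separated with `+`, unconstrained sites omitted and the `comp` site
#' dropped for top-level agents, then sorts the rule strings.  Two
#' compilations of the same model compare equal under this rendering
#' regardless of rule order and label choice.
#'
#' @param k A `kappa_program`.
#' @param rates Include `@ rate` in each line?
#' @return Sorted character vector, one canonical string per rule.
#' @export
kappa_canonical <- function(k, rates = TRUE) {
  out <- vapply(k$rules, function(r) {
    lhs <- canon_side(r$lhs)
    rhs <- canon_side(r$rhs)
    line <- paste0(lhs, " -> ", rhs)
    if (rates) line <- paste0(line, " @ ", num_str(r$rate))
    line
  }, "")
  sort(out, method = "radix")
}

#' Pair directed rules into reversible rules
#'
#' Two directed rules form a reversible pair when the canonical rendering of
#' one's left side equals the other's right side and vice versa (rates are
#' not compared).  Pairs are disjoint; each rule is used at most once.
#'
#' @param k A `kappa_program`.
#' @return A list with `n_pairs`, `n_rules`, and the index `pairs` matrix.
#' @export
pair_reversible <- function(k) {
  n <- length(k$rules)
  ls <- vapply(k$rules, function(r) canon_side(r$lhs), "")
  rs <- vapply(k$rules, function(r) canon_side(r$rhs), "")
  used <- logical(n)
  pairs <- NULL
  for (i in seq_len(n)) {
    if (used[[i]]) next
    for (j in seq_len(n)) {
      if (j == i || used[[j]]) next
      if (identical(ls[[i]], rs[[j]]) && identical(rs[[i]], ls[[j]])) {
        used[[i]] <- TRUE
        used[[j]] <- TRUE
        pairs <- rbind(pairs, c(i, j))
        break
      }
    }
  }
  list(n_pairs = if (is.null(pairs)) 0L else nrow(pairs),
       n_rules = n, pairs = pairs)
}
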