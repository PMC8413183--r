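# Exhaustive expression equivalence -------------------------------------------
#
# Used by the distillation checks and by the engine-vs-oracle tests: two
# expressions are equivalent on a finite atom domain iff they evaluate to
# the same Kleene value on every assignment of the domain.  Assignments are
# enumerated exhaustively, so the domain must stay small (<= 3^12 states by
# default).

# State space of one atom.  Findings touched by a grade predicate enumerate
# the joint (value, grade) states consistent with the data-model invariants:
# unknown, absent (grade 0), present with unrecorded grade, present graded
# 1..4.
atom_states <- function(atom) {
  switch(atom$kind,
    "finding" = {
      if (isTRUE(atom$graded)) {
        c(list(list(value = "unknown", grade = NULL),
               list(value = "absent", grade = NULL),
               list(value = "present", grade = NULL)),
          lapply(1:4, function(g) list(value = "present", grade = g)))
      } else {
        lapply(FINDING_STATES, function(v) list(value = v, grade = NULL))
      }
    },
    "test" = as.list(TEST_STATES),
    "course" = as.list(uv_courses()),
    "laterality" = as.list(uv_lateralities())
  )
}

# Build a uv_case from one assignment (a named list keyed like expr_atoms()).
assignment_case <- function(assignment, atoms) {
  findings <- list()
  tests <- list()
  course <- "unknown"
  laterality <- "unknown"
  for (key in names(atoms)) {
    atom <- atoms[[key]]
    st <- assignment[[key]]
    switch(atom$kind,
      "finding" = if (!identical(st$value, "unknown")) findings[[atom$code]] <- st,
      "test" = if (!identical(st, "unknown")) tests[[atom$code]] <- st,
      "course" = course <- st,
      "laterality" = laterality <- st
    )
  }
  uv_case("enum", anatomic_class = "anterior", course = course,
          laterality = laterality, findings = findings, tests = tests)
}

# Enumerate all assignments of a set of atoms; calls fn(case, assignment)
# for each.  Returns invisibly the number of assignments visited.
enumerate_assignments <- function(atoms, fn) {
  spaces <- lapply(atoms, atom_states)
  sizes <- vapply(spaces, length, 0L)
  total <- prod(sizes)
  idx <- rep(1L, length(spaces))
  n <- 0L
  repeat {
    assignment <- stats::setNames(
      lapply(seq_along(spaces), function(i) spaces[[i]][[idx[i]]]), names(atoms))
    fn(assignment_case(assignment, atoms), assignment)
    n <- n + 1L
    # odometer increment
    k <- 1L
    while (k <= length(idx)) {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= sizes[k]) break
      idx[k] <- 1L
      k <- k + 1L
    }
    if (k > length(idx)) break
  }
  invisible(n)
}

domain_size <- function(atoms) {
  prod(vapply(lapply(atoms, atom_states), length, 0L))
}

#' Exhaustive equivalence of two rule expressions
#'
#' True iff `a` and `b` evaluate to the same Kleene value on every
#' assignment of the union of their atom domains, by exhaustive
#' enumeration.  Refuses domains larger than `max_states` assignments.
#'
#' @param a,b `uv_expr` trees.
#' @param max_states Enumeration bound (default `3^12`).
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' x <- finding_is("heterochromia"); y <- finding_is("endotheliitis")
#' expr_equivalent(rx_or(x, rx_and(x, y)), x)  # absorption
expr_equivalent <- function(a, b, max_states = 3^12) {
  atoms <- expr_atoms(a)
  b_atoms <- expr_atoms(b)
  for (key in names(b_atoms)) {
    bt <- b_atoms[[key]]
    prev <- atoms[[key]]
    if (is.null(prev)) atoms[[key]] <- bt
    else if (isTRUE(bt$graded)) atoms[[key]]$graded <- TRUE
  }
  size <- domain_size(atoms)
  if (size > max_states)
    stop("domain too large for exhaustive equivalence: ", size,
         " assignments exceed the bound of ", max_states, call. = FALSE)
  equal <- TRUE
  enumerate_assignments(atoms, function(case, assignment) {
    if (equal && !identical(eval_expr(a, case), eval_expr(b, case)))
      equal <<- FALSE
  })
  equal
}
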