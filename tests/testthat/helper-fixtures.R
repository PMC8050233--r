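# Fixtures built in code: simple trace constructors and synthetic structures.

two_state_model <- function(p = 0.95, e = c(0.3, 0.7)) {
  sim_state_model(e, transition_probability = p)
}

# a bare trace tibble from explicit channel vectors
manual_trace <- function(I_DD, I_DA, I_AA, trace_id = "tr1") {
  tibble::tibble(trace_id = trace_id, frame = seq_along(I_DD) - 1L,
                 I_DD = I_DD, I_DA = I_DA, I_AA = I_AA)
}

# impose an acceptor bleach (optionally two-step) on a bleach-free trace
impose_acceptor_steps <- function(tr, steps) {
  # steps: named list frame -> multiplier applied from that frame on
  fac <- rep(1, nrow(tr))
  for (i in seq_along(steps$frame)) {
    fac[tr$frame >= steps$frame[i]] <- steps$level[i]
  }
  tr$I_AA <- tr$I_AA * fac
  tr$I_DA <- tr$I_DA * fac   # FRET disappears with the acceptor
  tr
}

# minimal PDB writer for synthetic structures (ATOM/HETATM records)
write_pdb_fixture <- function(path, atoms) {
  # atoms: tibble with type, atom, resid, chain, resno, x, y, z, element
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$type, i, a$atom, "", a$resid, a$chain, a$resno, "",
            a$x, a$y, a$z, 1.00, 0.00, a$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# ideal 100-residue poly-alanine helix backbone (N, CA, C per residue)
helix_atoms <- function(n_res = 100) {
  t <- seq_len(n_res)
  purrr::map_dfr(t, function(i) {
    ang <- 100 * pi / 180 * i
    tibble::tibble(
      type = "ATOM",
      atom = c("N", "CA", "C"),
      resid = "ALA", chain = "A", resno = i,
      x = 2.3 * cos(ang + c(-0.4, 0, 0.4)),
      y = 2.3 * sin(ang + c(-0.4, 0, 0.4)),
      z = 1.5 * i + c(-0.3, 0, 0.3),
      element = c("N", "C", "C")
    )
  })
}

# single isolated attachment atom at the origin
lone_atom_structure <- function() {
  s <- tibble::tibble(chain = "A", resno = 1L, resid = "CYS", atom = "CB",
                      x = 0, y = 0, z = 0, radius = 1.7)
  class(s) <- c("structure_model", class(s))
  s
}
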