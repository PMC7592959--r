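# Outward surface normals for mesh vertices of a solid, used to push
# boundary points off the surface.  The unit-frame normal cone is read off
# the primitive's implicit form; scaling transforms normals by 1/C,
# rotation carries them to the room frame.
outward_normals <- function(s, mesh) {
  R <- oracle_rotmat(s$rotation)
  P <- mesh_points(mesh)
  W <- sweep(P %*% R, 2L, s$translation)
  U <- sweep(W, 2L, s$scale, "/")
  N <- switch(s$kind,
    box = {
      M <- (abs(abs(U) - 0.5) < 1e-9) * sign(U)
      M
    },
    cylinder = {
      r <- sqrt(U[, 1]^2 + U[, 2]^2)
      radial <- (abs(r - 0.5) < 1e-9) & r > 0
      capped <- abs(abs(U[, 3]) - 0.5) < 1e-9
      cbind(ifelse(radial, U[, 1] / pmax(r, 1e-30), 0),
            ifelse(radial, U[, 2] / pmax(r, 1e-30), 0),
            ifelse(capped, sign(U[, 3]), 0))
    },
    ellipsoid = U
  )
  # gradient transform: divide by scale, rotate, normalise
  N <- sweep(N, 2L, s$scale, "/") %*% t(R)
  len <- sqrt(rowSums(N^2))
  N / pmax(len, 1e-30)
}

# Offset-parameterised plan around the shipped commissioning coordinates:
# returns a plan context whose safety-zone centre sits at room offset
# `off` = c(x, y, z) from the isocenter under the demo sign conventions.
plan_with_offset <- function(off, sz_shape = "box") {
  plan_context(c(lat = 103.1, ap = 4, si = 23.3),
               c(lat = 2 - off[1], ap = 1.8 + off[3], si = 0.8 + off[2]),
               sz_shape)
}

demo_cfg <- function() suppressWarnings(default_machine_config("demo"))
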