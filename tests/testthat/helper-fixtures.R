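# Shared fixture builders. Everything is generated in code at test time.

# uniform samples on a sphere surface, with outward normals
sphereCloud <- function(n = 5000, radius = 5, center = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  g <- matrix(rnorm(3 * n), ncol = 3)
  g <- g / sqrt(rowSums(g^2))
  pointCloud(sweep(g * radius, 2, center, "+"), normals = g)
}

# dense solid-sampled ball (interior + surface)
ballCloud <- function(n = 20000, radius = 5, seed = 1) {
  set.seed(seed)
  g <- matrix(rnorm(3 * n), ncol = 3)
  g <- g / sqrt(rowSums(g^2))
  r <- radius * runif(n)^(1 / 3)
  pointCloud(g * r)
}

# regular grid on the z = 0 plane
planeCloud <- function(nx = 40, ny = 40, pitch = 0.25) {
  g <- expand.grid(x = (seq_len(nx) - 1) * pitch, y = (seq_len(ny) - 1) * pitch)
  pointCloud(cbind(g$x, g$y, 0))
}

# closed-form volume of the union of two spheres of radius r at distance d
twoSphereUnionVolume <- function(r, d) {
  if (d >= 2 * r) return(2 * 4 / 3 * pi * r^3)
  lens <- pi * (2 * r - d)^2 * (d^2 + 4 * d * r) / (12 * d)
  2 * 4 / 3 * pi * r^3 - lens
}

# a small bunch + scan shared by the slower registration tests
smallBunchViews <- function(seed = 5, berries = 40, noiseSd = 0.2,
                            pointsPerView = 8000) {
  b <- generateBunch(bunchSpec(berryCount = berries, seed = seed))
  views <- scanViews(b, scanSpec(seed = seed + 500, noiseSd = noiseSd,
                                 pointsPerView = pointsPerView))
  list(bunch = b, views = views)
}

relErr <- function(x, ref) abs(x - ref) / abs(ref)
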