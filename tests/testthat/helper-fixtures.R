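# shared helpers: tiny elements and a cached body fixture

unit_hex <- function() {
  matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0,
           0, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1),
         8, 3, byrow = TRUE)
}

brick_hex <- function(a, b, c) unit_hex() %*% diag(c(a, b, c))

# one-hex assembly with a single part
single_hex_assembly <- function(corners = unit_hex(), density = 1e-6,
                                region = "torso") {
  hbm_assembly(
    nodes = data.frame(id = 1:8, x = corners[, 1], y = corners[, 2],
                       z = corners[, 3]),
    solids = data.frame(id = 1L, part = 1L, n1 = 1L, n2 = 2L, n3 = 3L,
                        n4 = 4L, n5 = 5L, n6 = 6L, n7 = 7L, n8 = 8L),
    parts = data.frame(id = 1L, name = "block", region = region,
                       material = "flesh", density = density))
}

random_rigid <- function() {
  # QR-based random rotation (caller controls the seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  rigid_transform(q, rnorm(3, sd = 50))
}

.fixture_cache <- new.env(parent = emptyenv())
get_fixture <- function() {
  if (is.null(.fixture_cache$fx))
    .fixture_cache$fx <- make_fixture_body()
  .fixture_cache$fx
}

fixture_impact_landmarks <- function() {
  labs <- c("mid_sternum", "T1", "T6", "T8", "L3", "glenohumeral_left",
            "glenohumeral_right", "xiphoid_process", "below_xiphoid_75mm",
            "greater_trochanter")
  landmark_set(labs, "torso", "skin",
               cbind(c(120, -120, -120, -120, -60, 0, 0, 110, 110, 120),
                     c(0, 0, 0, 0, 0, 120, -120, 60, 60, 60),
                     c(280, 290, 230, 200, 140, 300, 300, 240, 165, 60)))
}
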