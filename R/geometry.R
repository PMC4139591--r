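## Internal geometry utilities: vectors in rows, Angstrom / degrees.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

## dihedral angle (degrees, in (-180, 180]) for four points
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

## vectorized dihedrals: p1..p4 are n x 3 matrices
dihedral_angles <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2) / sqrt(rowSums(b2 * b2))
  rad2deg(atan2(rowSums(m1 * n2), rowSums(n1 * n2)))
}

## Natural extension reference frame: place atom d given positions a, b, c,
## bond |c-d|, angle b-c-d (degrees) and dihedral a-b-c-d (degrees).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- deg2rad(angle); ph <- deg2rad(dihedral)
  d_local <- c(-bond * cos(th),
               bond * sin(th) * cos(ph),
               -bond * sin(th) * sin(ph))
  bc <- unitv(c - b)
  n <- unitv(c(
    (b - a)[2] * bc[3] - (b - a)[3] * bc[2],
    (b - a)[3] * bc[1] - (b - a)[1] * bc[3],
    (b - a)[1] * bc[2] - (b - a)[2] * bc[1]))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  rot <- cbind(bc, m, n)
  as.numeric(rot %*% d_local + c)
}

## rotation matrix from ZYZ Euler angles (radians)
euler_zyz <- function(a, b, g) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  matrix(c(ca * cb * cg - sa * sg, -ca * cb * sg - sa * cg, ca * sb,
           sa * cb * cg + ca * sg, -sa * cb * sg + ca * cg, sa * sb,
           -sb * cg, sb * sg, cb),
         nrow = 3, byrow = TRUE)
}

## uniform random rotation matrix from a random unit quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

## squared cross distances between row-point matrices a (n x 3) and b (m x 3)
cross_dist2 <- function(a, b) {
  a2 <- rowSums(a * a); b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  d2
}

## deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## --- constant tables -------------------------------------------------------

## van der Waals radii (Angstrom)
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

## Kyte-Doolittle hydropathy scale
.kd_scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

## average residue masses (Da); peptide MW = sum + one water
.residue_mass <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                   C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                   H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                   M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                   T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.water_mass <- 18.0153

## EMBOSS pKa set for the Henderson-Hasselbalch net-charge function
.pka_nterm <- 8.6
.pka_cterm <- 3.6
.pka_pos <- c(K = 10.8, R = 12.5, H = 6.5)
.pka_neg <- c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

## maximal ASA per residue type (Gly-X-Gly extended reference, Angstrom^2)
.max_asa <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLU = 223, GLN = 225, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
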