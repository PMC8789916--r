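# Shared builders for small in-code fixtures.

# one canonical SR vial row with adjustable fields
make_vial <- function(activity_product_bq = 50,
                      activity_substrate_bq = 9950,
                      pool_total_mol = 2.5e-5, alpha = 1.06,
                      bulk_density_g_cm3 = 2, time_d = 10, mass_g = 10,
                      assay = "SR", sample_id = "v1", depth_mbsf = 500) {
  data.frame(sample_id = sample_id, assay = assay, depth_mbsf = depth_mbsf,
             activity_product_bq = activity_product_bq,
             activity_substrate_bq = activity_substrate_bq,
             pool_total_mol = pool_total_mol, alpha = alpha,
             bulk_density_g_cm3 = bulk_density_g_cm3,
             time_d = time_d, mass_g = mass_g,
             stringsAsFactors = FALSE)
}

# direct re-evaluation of the rate equation, kept deliberately separate
# from the package implementation
rate_by_hand <- function(ap, as, pool, alpha, rho, t, m) {
  ap / (ap + as) * pool * alpha * rho / (t * m) * 1e12
}
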