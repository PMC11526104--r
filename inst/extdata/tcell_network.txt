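# Compartmentalized central-carbon network for activated CD4+ T cells
# traced with [U-13C]glucose.  Documented reconstruction: glycolysis,
# glycerol-3-phosphate shunt, lactate/alanine exchange, mitochondrial
# pyruvate metabolism (PDH, pyruvate carboxylase, malic enzyme), TCA
# cycle with succinate/fumarate rotational symmetry, glutamine
# anaplerosis, citrate export (ATP-citrate lyase) feeding cytosolic
# OAA/malate/aspartate, CO2 and extracellular-pyruvate dilution, and
# extraction-mixing pools for the six dual-compartment metabolites.
# Compartment suffixes: .x extracellular/source-sink, .c cytosol,
# .m mitochondrion, .obs extraction measurement pool.
# Flux units: nmol per 1e6 cells per hour.

metabolite GLC.x carbons=6 balanced=no
metabolite PYR.x carbons=3 balanced=no
metabolite LAC.x carbons=3 balanced=no
metabolite ALA.x carbons=3 balanced=no
metabolite GLN.x carbons=5 balanced=no
metabolite GLU.x carbons=5 balanced=no
metabolite ASP.x carbons=4 balanced=no
metabolite ACA.x carbons=2 balanced=no
metabolite CO2.x carbons=1 balanced=no

metabolite G6P.c carbons=6 balanced=yes
metabolite F6P.c carbons=6 balanced=yes
metabolite FBP.c carbons=6 balanced=yes
metabolite DHAP.c carbons=3 balanced=yes
metabolite GAP.c carbons=3 balanced=yes
metabolite G3P.c carbons=3 balanced=no
metabolite PG3.c carbons=3 balanced=yes
metabolite PEP.c carbons=3 balanced=yes
metabolite PYR.c carbons=3 balanced=yes
metabolite LAC.c carbons=3 balanced=yes
metabolite ALA.c carbons=3 balanced=yes
metabolite GLN.c carbons=5 balanced=yes
metabolite GLU.c carbons=5 balanced=yes
metabolite CIT.c carbons=6 balanced=yes
metabolite OAA.c carbons=4 balanced=yes
metabolite MAL.c carbons=4 balanced=yes
metabolite ASP.c carbons=4 balanced=yes
metabolite ACA.c carbons=2 balanced=yes

metabolite PYR.m carbons=3 balanced=yes
metabolite ALA.m carbons=3 balanced=yes
metabolite ACA.m carbons=2 balanced=yes
metabolite CIT.m carbons=6 balanced=yes
metabolite AKG.m carbons=5 balanced=yes
metabolite SUC.m carbons=4 balanced=yes
metabolite FUM.m carbons=4 balanced=yes
metabolite MAL.m carbons=4 balanced=yes
metabolite OAA.m carbons=4 balanced=yes
metabolite ASP.m carbons=4 balanced=yes
metabolite GLU.m carbons=5 balanced=yes
metabolite CO2.m carbons=1 balanced=yes

metabolite PYR.obs carbons=3 balanced=no
metabolite ALA.obs carbons=3 balanced=no
metabolite MAL.obs carbons=4 balanced=no
metabolite ASP.obs carbons=4 balanced=no
metabolite GLU.obs carbons=5 balanced=no
metabolite CIT.obs carbons=6 balanced=no

tracer GLC.x

# glycolysis (upper glycolysis treated as irreversible: with uniformly
# labeled glucose its exchange fluxes do not move any measured MID)
v_glut: GLC.x (abcdef) -> G6P.c (abcdef)
v_pgi: G6P.c (abcdef) -> F6P.c (abcdef)
v_pfk: F6P.c (abcdef) -> FBP.c (abcdef)
v_ald: FBP.c (abcdef) -> DHAP.c (cba) + GAP.c (def)
v_tpi: DHAP.c (abc) -> GAP.c (abc)
v_gapd: GAP.c (abc) -> PG3.c (abc)
v_eno: PG3.c (abc) -> PEP.c (abc)
v_pyk: PEP.c (abc) -> PYR.c (abc)

# glycerol-3-phosphate: a labeling readout of DHAP.  The shunt flux
# itself is unidentifiable from these data (a single-producer pool
# carries its parent's MID at any flux), so the pool is flux-free.
m_g3p: DHAP.c (abc) -> G3P.c (abc) kind=measurement-pool

# lactate and alanine
v_ldh: PYR.c (abc) -> LAC.c (abc) reversible
v_lacs: LAC.c (abc) -> LAC.x (abc)
v_alat_c: PYR.c (abc) -> ALA.c (abc) reversible
v_alat_m: PYR.m (abc) -> ALA.m (abc) reversible
v_alas: ALA.c (abc) -> ALA.x (abc)

# pyruvate compartments and extracellular exchange (dilution)
v_pyrx: PYR.x (abc) -> PYR.c (abc) reversible kind=dilution
v_pyrt: PYR.c (abc) -> PYR.m (abc) reversible

# mitochondrial pyruvate metabolism
v_pdh: PYR.m (abc) -> CO2.m (a) + ACA.m (bc)
v_pc: PYR.m (abc) + CO2.m (d) -> OAA.m (abcd)
v_me: MAL.m (abcd) -> PYR.m (abc) + CO2.m (d)

# TCA cycle; succinate/fumarate rotational symmetry as 50/50 variants
v_cs: OAA.m (abcd) + ACA.m (ef) -> CIT.m (dcbfea)
v_idh: CIT.m (abcdef) -> AKG.m (abcde) + CO2.m (f)
v_akgd: AKG.m (abcde) -> CO2.m (a) + SUC.m (bcde|edcb)
v_sdh: SUC.m (abcd) -> FUM.m (abcd)
v_fum: FUM.m (abcd) -> MAL.m (abcd|dcba) reversible
v_mdh: MAL.m (abcd) -> OAA.m (abcd) reversible
v_got_m: OAA.m (abcd) -> ASP.m (abcd) reversible

# glutamine / glutamate
v_glnup: GLN.x (abcde) -> GLN.c (abcde)
v_glnase: GLN.c (abcde) -> GLU.c (abcde) reversible
v_glut_t: GLU.c (abcde) -> GLU.m (abcde) reversible
v_gdh: AKG.m (abcde) -> GLU.m (abcde) reversible
v_glus: GLU.c (abcde) -> GLU.x (abcde)

# citrate export, cytosolic OAA/malate/aspartate
v_cit_t: CIT.m (abcdef) -> CIT.c (abcdef)
v_acl: CIT.c (abcdef) -> OAA.c (abcd) + ACA.c (ef)
v_lip: ACA.c (ab) -> ACA.x (ab)
v_mdh_c: OAA.c (abcd) -> MAL.c (abcd)
v_mal_t: MAL.c (abcd) -> MAL.m (abcd)
v_got_c: OAA.c (abcd) -> ASP.c (abcd) reversible
v_asp_t: ASP.m (abcd) -> ASP.c (abcd)
v_asps: ASP.c (abcd) -> ASP.x (abcd)

# unlabeled CO2 dilution
v_co2x: CO2.x (a) -> CO2.m (a) reversible kind=dilution

# extraction mixing (flux-free; fraction = cytosolic share)
m_pyr: PYR.c (abc) + PYR.m (abc) -> PYR.obs (abc) kind=mixing
m_ala: ALA.c (abc) + ALA.m (abc) -> ALA.obs (abc) kind=mixing
m_mal: MAL.c (abcd) + MAL.m (abcd) -> MAL.obs (abcd) kind=mixing
m_asp: ASP.c (abcd) + ASP.m (abcd) -> ASP.obs (abcd) kind=mixing
m_glu: GLU.c (abcde) + GLU.m (abcde) -> GLU.obs (abcde) kind=mixing
m_cit: CIT.c (abcdef) + CIT.m (abcdef) -> CIT.obs (abcdef) kind=mixing
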