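# Probabilistic logic network of TRAIL-receptor-agonist-induced signalling in
# melanoma: death-receptor apoptosis, NFkB survival signalling and MAPK/PI3K
# growth pathways with their crosstalk. 19 nodes, 29 interactions.
# Reconstructed topology: the three inhibitory reactions onto the cleaved
# caspases are as described for the published model; remaining edges follow
# the canonical pathway chains and are tuned to the published node and
# parameter counts (synthetic reconstruction, not the deposited file).
@node IZI1551 input
@node BRAF latent constitutive
@node PI3K latent constitutive
@node DR latent
@node Casp8cl latent
@node Casp3cl latent
@node MOMP latent
@node SMAC latent
@node BCL2 latent
@node IKK latent
@node MEK latent
@node AKT measured
@node ERK measured
@node FLIP measured
@node XIAP measured
@node IkBa measured
@node NFkB measured
@node PARPcl measured
@node Apoptosis readout

# extrinsic apoptosis
IZI1551 -> DR        k_izi_dr
DR      -> Casp8cl   k_dr_c8
FLIP    -| Casp8cl   k_flip_c8
Casp8cl -> Casp3cl   k_c8_c3
MOMP    -> Casp3cl   k_momp_c3
XIAP    -| Casp3cl   k_xiap_c3
BCL2    -| Casp3cl   k_bcl2_c3
Casp8cl -> MOMP      k_c8_momp
BCL2    -| MOMP      k_bcl2_momp
MOMP    -> SMAC      k_momp_smac
SMAC    -| XIAP      k_smac_xiap
Casp3cl -> PARPcl    k_c3_parp
Casp3cl -> Apoptosis k_c3_apo
AKT     -| Apoptosis k_akt_apo

# NFkB survival branch with the IkBa negative feedback
DR   -> IKK   k_dr_ikk
IKK  -| IkBa  k_ikk_ikb
NFkB -> IkBa  k_nfkb_ikb
IkBa -| NFkB  k_ikb_nfkb
IKK  -> NFkB  k_ikk_nfkb
AKT  -> NFkB  k_akt_nfkb
NFkB -> FLIP  k_nfkb_flip
ERK  -> FLIP  k_erk_flip
NFkB -> XIAP  k_nfkb_xiap
AKT  -> XIAP  k_akt_xiap
NFkB -> BCL2  k_nfkb_bcl2
ERK  -> BCL2  k_erk_bcl2

# MAPK and PI3K growth signalling
BRAF -> MEK  k_braf_mek
MEK  -> ERK  k_mek_erk
PI3K -> AKT  k_pi3k_akt
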