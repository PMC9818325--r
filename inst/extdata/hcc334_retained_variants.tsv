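sample_id	gene	variant_id	quality	in_repeat_region	consequence	intron_offset	in_last_exon	maf_supercontrols	maf_gnomad	maf_1000g	maf_esp	maf_exac	clinvar	known_sequencing_error	known_pathogenic_whitelisted
P001	PMS2	PMS2:c.1144+250_2175-1948del8907	500	FALSE	cnv_deletion	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P002	NBN	NBN:c.657del5(p.Lys219fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	pathogenic	FALSE	TRUE
P003	NBN	NBN:c.657del5(p.Lys219fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	pathogenic	FALSE	TRUE
P004	NBN	NBN:c.657del5(p.Lys219fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	pathogenic	FALSE	TRUE
P005	NBN	NBN:c.657del5(p.Lys219fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	pathogenic	FALSE	TRUE
P006	FH	FH:c.1127A>C(p.Gln376Pro)	500	FALSE	missense	0	FALSE	0	0	NA	NA	NA	pathogenic	FALSE	FALSE
P007	RET	RET:c.2304G>C(p.Glu768Asp)	500	FALSE	missense	0	FALSE	0	0	NA	NA	NA	pathogenic	FALSE	FALSE
P008	DMBT1	DMBT1:c.2177-2A>C	500	FALSE	canonical_splice	-2	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P009	DMBT1	DMBT1:c.4828+1G>A	500	FALSE	canonical_splice	1	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P010	DMBT1	DMBT1:c.4611C>G(p.Tyr1537Ter)	500	FALSE	stop_gained	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P011	RAD50	RAD50:c.1875C>G(p.Tyr625Ter)	500	FALSE	stop_gained	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P012	RAD50	RAD50:c.2043delC(p.Val683fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P013	RAD50	RAD50:c.2521del9(p.Thr841fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P013	ATRIP	ATRIP:c.1152del4(p.Gly385fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P014	ATRIP	ATRIP:c.1870del2(p.Cys624fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P015	BLM	BLM:c.1642C>T(p.Gln548Ter)	500	FALSE	stop_gained	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P016	BLM	BLM:c.1642C>T(p.Gln548Ter)	500	FALSE	stop_gained	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P017	ERCC2	ERCC2:c.2150C>G(r.2144_2190del45)	500	FALSE	missense	0	FALSE	0	0	NA	NA	NA	likely_pathogenic	FALSE	FALSE
P018	ERCC2	ERCC2:c.2150C>G(r.2144_2190del45)	500	FALSE	missense	0	FALSE	0	0	NA	NA	NA	likely_pathogenic	FALSE	FALSE
P019	LIG3	LIG3:c.1283delT(p.His428fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P020	LIG3	LIG3:c.799C>T(p.Arg267Ter)	500	FALSE	stop_gained	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P021	MSH3	MSH3:c.2686G>T(p.Gly896Ter)	500	FALSE	stop_gained	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P022	MSH3	MSH3:c.1480delA(p.Asn494fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P023	SLX4	SLX4:c.4207G>T(p.Glu1403Ter)	500	FALSE	stop_gained	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P024	SLX4	SLX4:c.4024delA(p.Ser1342fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P025	AXIN1	AXIN1:c.64C>T(p.Arg22Ter)	500	FALSE	stop_gained	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P026	ERCC5	ERCC5:c.3285del10(p.Ser1096fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P027	ERCC6	ERCC6:c.537T>A(p.Tyr179Ter)	500	FALSE	stop_gained	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P028	EXO1	EXO1:c.1578del2(p.Asp526fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P029	FANCA	FANCA:del16-17	500	FALSE	cnv_deletion	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P030	FANCD2	FANCD2:c.990-1G>A	500	FALSE	canonical_splice	-1	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P031	FANCG	FANCG:c.313G>T(p.Glu105Ter)	500	FALSE	stop_gained	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P032	HOXB13	HOXB13:c.251G>A(p.Gly84Glu)	500	FALSE	missense	0	FALSE	0	0	NA	NA	NA	pathogenic	FALSE	FALSE
P033	MCPH1	MCPH1:c.126del2(p.Phe43fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P034	MDC1	MDC1:c.6081delC(p.Ser2028fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P035	MMP8	MMP8:c.460G>T(p.Gly154Ter)	500	FALSE	stop_gained	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P036	MLH3	MLH3:c.3393dup2(p.Thr1132fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P037	NHEJ1	NHEJ1:c.169C>T(p.Arg57Ter)	500	FALSE	stop_gained	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P038	PIK3CG	PIK3CG:c.2519del2(p.Gln840fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P039	PMS1	PMS1:c.1009insA(p.Tyr337fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P040	RAD1	RAD1:c.168del5(p.Lys57fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P041	RECQL5	RECQL5:c.2308C>T(p.Arg770Ter)	500	FALSE	stop_gained	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P042	SBDS	SBDS:c.258+2T>C	500	FALSE	canonical_splice	2	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P043	SETX	SETX:c.5074dup2(p.Leu1692fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P044	SMARCA4	SMARCA4:c.859+1G>A	500	FALSE	canonical_splice	1	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P045	TLR2	TLR2:c.1339C>T(p.Arg447Ter)	500	FALSE	stop_gained	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P046	TLR4	TLR4:c.261-1G>C	500	FALSE	canonical_splice	-1	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
P047	XRCC1	XRCC1:c.406dupT(p.Tyr136fs)	500	FALSE	frameshift	0	FALSE	0	0	NA	NA	NA	none	FALSE	FALSE
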