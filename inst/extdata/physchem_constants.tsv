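species	parameter	value	units	citation
general	T_ref	298.15	K	reference temperature for all parameter values
general	R_gas	8.31446	J mol-1 K-1	CODATA
general	P_atm	101325	Pa	standard atmosphere
general	gas_diff_T_exponent	1.75	-	Fuller-type power-law temperature scaling of binary gas diffusivities
general	water_visc_Ea_R	1900	K	effective activation temperature of water viscosity, Stokes-Einstein scaling of aqueous diffusivities
water	pKw_A	4470.99	K	Harned & Owen (1958) ion product of water, pKw = A/T + B + C*T
water	pKw_B	-6.0875	-	Harned & Owen (1958)
water	pKw_C	0.01706	K-1	Harned & Owen (1958)
COS	d_air_ref	1.27e-05	m2 s-1	COS-air binary diffusivity at 25 C, Massman (1998)
COS	d_water_ref	1.94e-09	m2 s-1	COS aqueous diffusivity at 25 C, Ulshofer et al. (1996)
COS	B_ref	0.489	-	dimensionless Henry solubility (aqueous/gas) at 25 C, from KH = 0.020 M atm-1, Elliott et al. (1989)
COS	B_dH_R	3300	K	van 't Hoff temperature slope of COS solubility, Elliott et al. (1989)
COS	kw_lnA	24.3	ln(s-1)	neutral hydrolysis pathway, k_w = exp(lnA - Ea_R/T), Elliott et al. (1989)
COS	kw_Ea_R	10450	K	neutral hydrolysis activation temperature, Elliott et al. (1989)
COS	koh_lnA	22.8	ln(M-1 s-1)	alkaline hydrolysis pathway, k_OH = exp(lnA - Ea_R/T), Elliott et al. (1989)
COS	koh_Ea_R	6040	K	alkaline hydrolysis activation temperature, Elliott et al. (1989)
CO2	d_air_ref	1.55e-05	m2 s-1	CO2-air binary diffusivity at 25 C, Massman (1998)
CO2	d_water_ref	1.91e-09	m2 s-1	CO2 aqueous diffusivity at 25 C, Jahne et al. (1987)
CO2	B_ref	0.831	-	dimensionless Henry solubility at 25 C, from KH = 0.034 M atm-1, Weiss (1974)
CO2	B_dH_R	2400	K	van 't Hoff temperature slope of CO2 solubility, Weiss (1974)
CO2	kh_ref	0.037	s-1	CO2 hydration rate at 25 C, Johnson (1982)
CO2	kh_Ea_R	8850	K	hydration activation temperature, Johnson (1982)
CO2	koh_ref	8500	M-1 s-1	CO2 + OH- hydroxylation rate at 25 C, Pinsent et al. (1956)
CO2	koh_Ea_R	6850	K	hydroxylation activation temperature, Pinsent et al. (1956)
CO2	pK1	6.35	-	first dissociation constant of carbonic acid, freshwater 25 C, Stumm & Morgan (1996)
CO2	pK2	10.33	-	second dissociation constant, Stumm & Morgan (1996)
CO2	iso_exchange_yield	0.3333333333333333	-	one in three hydration events exchanges the labelled oxygen, Mills & Urey (1940)
isotope	R18_VSMOW	0.0020052	-	18O/16O ratio of VSMOW, Baertschi (1976)
isotope	R18_VPDBCO2	0.0020884	-	18O/16O ratio of VPDB-CO2 reference
isotope	eps_eq_A	17604	K	CO2-water 18O equilibrium fractionation, eps = A/T + B (permil), Brenninkmeijer et al. (1983)
isotope	eps_eq_B	-17.93	permil	Brenninkmeijer et al. (1983)
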