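exposure	rsid	gene	chr	ea	nea	beta_exp	se_exp	p_exp	beta_out	se_out	p_out	var_explained_pct
alpha-linolenic acid	rs174547	FADS1	11	C	T	0.02	0.001	3.5e-64	-0.011	0.008	0.158	1.0
eicosapentaenoic acid	rs3798713	ELOVL2	6	C	G	0.04	0.005	1.9e-12	0.002	0.008	0.797	0.4
eicosapentaenoic acid	rs174538	C11orf10	11	G	A	0.08	0.005	5.4e-58	0.014	0.008	0.073	1.7
docosapentaenoic acid	rs780094	GCKR	2	T	C	0.02	0.003	9.0e-9	-0.008	0.007	0.295	0.5
docosapentaenoic acid	rs3734398	ELOVL2	6	C	T	0.04	0.003	9.7e-43	-0.002	0.007	0.798	2.7
docosapentaenoic acid	rs174547	FADS1	11	T	C	0.08	0.003	3.8e-154	0.011	0.008	0.158	8.4
docosahexaenoic acid	rs2236212	ELOVL2	6	G	C	0.11	0.014	1.3e-15	-0.002	0.007	0.816	0.7
linoleic acid	rs10740118	JMJD1C	10	G	C	0.25	0.05	8.1e-9	-0.047	0.007	4.9e-11	0.2-0.7
linoleic acid	rs174547	FADS1	11	C	T	1.47	0.05	5.0e-274	-0.011	0.008	0.158	7.6-18.1
linoleic acid	rs16966952	NTAN1	16	G	A	0.35	0.04	1.2e-15	-0.004	0.008	0.583	0.5-2.5
arachidonic acid	rs174547	FADS1	11	T	C	1.69	0.02	3.3e-971	0.011	0.008	0.158	3.7-37.6
arachidonic acid	rs16966952	NTAN1	16	G	A	0.2	0.03	2.4e-10	-0.004	0.008	0.583	0.1-0.6
palmitoleic acid	rs780093	GCKR	2	T	C	0.02	0.003	9.8e-10	-0.007	0.007	0.312	0.2-0.9
palmitoleic acid	rs6722456	RN7SKP93	2	G	A	0.05	0.009	4.1e-8	0.006	0.02	0.765	0.01-0.6
palmitoleic acid	rs603424	SCD/PKD2L1	10	G	A	0.03	0.004	5.7e-15	0.038	0.01	8.5e-5	0.3-1.6
palmitoleic acid	rs11190604	HIF1AN	10	G	A	0.02	0.004	5.7e-9	-0.012	0.009	0.179	0.02-0.7
palmitoleic acid	rs102275	FADS1/2	11	C	T	0.02	0.003	6.6e-13	-0.011	0.007	0.136	0.15-1.0
oleic acid	rs102275	FADS1/2	11	C	T	0.23	0.02	2.2e-32	-0.011	0.007	0.136	0.3-2.1
palmitic acid	rs2391388	ALG14	1	C	A	0.18	0.03	2.7e-11	0.013	0.007	0.087	0.2-1.0
stearic acid	rs6675668	ALG14	1	G	T	0.17	0.02	2.2e-18	-0.011	0.007	0.121	0.4-1.4
stearic acid	rs11119805	LPGAT1	1	T	A	0.17	0.03	2.8e-9	0.008	0.011	0.435	0.01-0.7
stearic acid	rs102275	FADS1/2	11	T	C	0.18	0.02	1.3e-20	0.011	0.007	0.136	0.3-1.2
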