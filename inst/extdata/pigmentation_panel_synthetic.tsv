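rsID	chrom	pos	ref	alt	significance	condition
rs12913832	15	28365618	A	G	pigmentation-associated	eye color
rs1805007	16	89986117	C	T	pigmentation-associated	hair color
rs1805008	16	89986144	C	T	pigmentation-associated	skin pigmentation
rs16891982	5	33951693	C	G	pigmentation-associated	eye color
rs1426654	15	48426484	A	G	pigmentation-associated	hair color
rs12203592	6	396321	C	T	pigmentation-associated	skin pigmentation
rs1042602	11	88911696	C	A	pigmentation-associated	eye color
rs4959270	6	457748	C	A	pigmentation-associated	hair color
rs28777	5	33958959	C	A	pigmentation-associated	skin pigmentation
rs683	9	12709305	A	C	pigmentation-associated	eye color
rsP0001	1	20137911	C	T	pigmentation-associated	hair color
rsP0002	2	20275822	G	A	pigmentation-associated	skin pigmentation
rsP0003	3	20413733	A	G	pigmentation-associated	eye color
rsP0004	4	20551644	T	C	pigmentation-associated	hair color
rsP0005	5	20689555	C	T	pigmentation-associated	skin pigmentation
rsP0006	6	20827466	G	A	pigmentation-associated	eye color
rsP0007	7	20965377	A	G	pigmentation-associated	hair color
rsP0008	8	21103288	T	C	pigmentation-associated	skin pigmentation
rsP0009	9	21241199	C	T	pigmentation-associated	eye color
rsP0010	10	21379110	G	A	pigmentation-associated	hair color
rsP0011	11	21517021	A	G	pigmentation-associated	skin pigmentation
rsP0012	12	21654932	T	C	pigmentation-associated	eye color
rsP0013	13	21792843	C	T	pigmentation-associated	hair color
rsP0014	14	21930754	G	A	pigmentation-associated	skin pigmentation
rsP0015	15	22068665	A	G	pigmentation-associated	eye color
rsP0016	16	22206576	T	C	pigmentation-associated	hair color
rsP0017	17	22344487	C	T	pigmentation-associated	skin pigmentation
rsP0018	18	22482398	G	A	pigmentation-associated	eye color
rsP0019	19	22620309	A	G	pigmentation-associated	hair color
rsP0020	20	22758220	T	C	pigmentation-associated	skin pigmentation
rsP0021	21	22896131	C	T	pigmentation-associated	eye color
rsP0022	22	23034042	G	A	pigmentation-associated	hair color
rsP0023	1	23171953	A	G	pigmentation-associated	skin pigmentation
rsP0024	2	23309864	T	C	pigmentation-associated	eye color
rsP0025	3	23447775	C	T	pigmentation-associated	hair color
rsP0026	4	23585686	G	A	pigmentation-associated	skin pigmentation
rsP0027	5	23723597	A	G	pigmentation-associated	eye color
rsP0028	6	23861508	T	C	pigmentation-associated	hair color
rsP0029	7	23999419	C	T	pigmentation-associated	skin pigmentation
rsP0030	8	24137330	G	A	pigmentation-associated	eye color
rsP0031	9	24275241	A	G	pigmentation-associated	hair color
rsP0032	10	24413152	T	C	pigmentation-associated	skin pigmentation
rsP0033	11	24551063	C	T	pigmentation-associated	eye color
rsP0034	12	24688974	G	A	pigmentation-associated	hair color
rsP0035	13	24826885	A	G	pigmentation-associated	skin pigmentation
rsP0036	14	24964796	T	C	pigmentation-associated	eye color
rsP0037	15	25102707	C	T	pigmentation-associated	hair color
rsP0038	16	25240618	G	A	pigmentation-associated	skin pigmentation
rsP0039	17	25378529	A	G	pigmentation-associated	eye color
rsP0040	18	25516440	T	C	pigmentation-associated	hair color
rsP0041	19	25654351	C	T	pigmentation-associated	skin pigmentation
rsP0042	20	25792262	G	A	pigmentation-associated	eye color
rsP0043	21	25930173	A	G	pigmentation-associated	hair color
rsP0044	22	26068084	T	C	pigmentation-associated	skin pigmentation
rsP0045	1	26205995	C	T	pigmentation-associated	eye color
rsP0046	2	26343906	G	A	pigmentation-associated	hair color
rsP0047	3	26481817	A	G	pigmentation-associated	skin pigmentation
rsP0048	4	26619728	T	C	pigmentation-associated	eye color
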