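concept_id	name	semantic_type
LK0001	osteoarthritis	cond
LK0001	knee osteoarthritis	cond
LK0001	arthritis	cond
LK0002	ACL tear	cond
LK0002	ACL rupture	cond
LK0002	torn ACL	cond
LK0002	ruptured ACL	cond
LK0003	completely ruptured	cond
LK0004	meniscus tear	cond
LK0004	torn meniscus	cond
LK0004	torn cartilage	cond
LK0005	cartilage damage	cond
LK0006	patellofemoral pain syndrome	cond
LK0006	runner's knee	cond
LK0007	tendinitis	cond
LK0007	tendonitis	cond
LK0008	bursitis	cond
LK0009	sprain	cond
LK0009	sprained knee	cond
LK0010	ligament injury	cond
LK0011	dislocated kneecap	cond
LK0011	patellar dislocation	cond
LK0011	dislocation	cond
LK0012	fracture	cond
LK0012	fractured patella	cond
LK0013	injury	cond
LK0014	MCL strain	cond
LK0101	ACL	anat
LK0101	anterior cruciate ligament	anat
LK0102	knee	anat
LK0102	knee joint	anat
LK0103	kneecap	anat
LK0103	patella	anat
LK0104	meniscus	anat
LK0105	cartilage	anat
LK0106	hamstring	anat
LK0107	quadriceps	anat
LK0107	quads	anat
LK0108	ligament	anat
LK0109	tendon	anat
LK0110	MCL	anat
LK0110	medial collateral ligament	anat
LK0201	reconstruction surgery	surg
LK0202	hamstring graft	surg
LK0203	knee replacement	surg
LK0203	total knee replacement	surg
LK0204	arthroscopy	surg
LK0204	keyhole surgery	surg
LK0205	meniscus repair	surg
LK0206	operation	surg
LK0207	surgery	surg
LK0301	physiotherapy	thpr
LK0301	physio	thpr
LK0302	hydrotherapy	thpr
LK0303	acupuncture	thpr
LK0304	massage	thpr
LK0305	steroid injection	thpr
LK0305	cortisone injection	thpr
LK0306	ice	thpr
LK0306	icing	thpr
LK0307	rest	thpr
LK0308	knee strapping	thpr
LK0401	ibuprofen	drug
LK0402	paracetamol	drug
LK0402	acetaminophen	drug
LK0403	naproxen	drug
LK0404	codeine	drug
LK0405	painkillers	drug
LK0405	painkiller	drug
LK0406	anti-inflammatories	drug
LK0501	knee brace	devi
LK0501	brace	devi
LK0502	crutches	devi
LK0502	crutch	devi
LK0503	support bandage	devi
LK0503	tubigrip	devi
LK0504	walking stick	devi
LK0601	cardiovascular exercises	exac
LK0601	cardio	exac
LK0602	stretching	exac
LK0602	stretches	exac
LK0603	strengthening exercises	exac
LK0604	quad exercises	exac
LK0605	leg raises	exac
LK0606	balance exercises	exac
LK0701	pain	sosy
LK0702	ache	sosy
LK0702	aching	sosy
LK0703	stiffness	sosy
LK0704	swelling	sosy
LK0704	edema	sosy
LK0704	oedema	sosy
LK0705	bruising	sosy
LK0706	clicking	sosy
LK0707	popping	sosy
LK0708	locking	sosy
LK0709	grinding	sosy
LK0710	giving way	sosy
LK0711	instability	sosy
LK0712	weakness	sosy
LK0713	numbness	sosy
LK0714	tingling	sosy
LK0715	discomfort	sosy
LK0801	exercise	dora
LK0802	hobbies	dora
LK0802	hobby	dora
LK0803	squash	dora
LK0804	golf	dora
LK0805	tennis	dora
LK0806	football	dora
LK0807	rugby	dora
LK0808	cricket	dora
LK0809	netball	dora
LK0810	badminton	dora
LK0811	yoga	dora
LK0812	gym	dora
LK0813	gardening	dora
LK0814	swimming	dora
LK0815	cycling	dora
LK0816	running	dora
LK0817	walking	dora
LK0818	housework	dora
LK0819	shopping	dora
LK0820	driving	dora
LK0901	job	ocdi
LK0902	profession	ocdi
LK0903	career	ocdi
LK1001	work	ocac
LK1002	manual work	ocac
LK1003	desk work	ocac
LK1101	vehicle mechanic	prog
LK1102	mechanic	prog
LK1103	teacher	prog
LK1104	nurse	prog
LK1105	builder	prog
LK1106	electrician	prog
LK1107	plumber	prog
LK1108	accountant	prog
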