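Gene_ID	Position	EUCO_F1	EUCO_F2	EUCO_F3	EUCO_M1	EUCO_M2	EUCO_M3	Regulation
Cluster-47702.80936	1101	C	C	C	G	G	G	Male-biased expression
Cluster-47702.80197	360	T	T	T	C	C	C	Male-biased expression
Cluster-47702.80197	460	G	G	G	A	A	A	
Cluster-47702.38156	538	T	T	T	C	C	C	Male-biased expression
Cluster-47702.38156	596	G	G	G	T	T	T	
Cluster-47702.79497	297	A	A	A	G	G	G	Male-biased expression
Cluster-47702.79497	312	C	C	C	T	T	T	
Cluster-47702.45188	947	T	T	T	G	G	G	Male-biased expression
Cluster-47702.45188	968	T	T	T	C	C	C	
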