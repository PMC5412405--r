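Case,Age,Gender,Histological Subtype,Infiltration Pattern,M Stage,N Stage
1,91,female,anaplastic,trachea,0,1
2,60,female,papillary,trachea,0,1
3,73,male,papillary,"trachea, esophagus",0,1
4,68,female,papillary,"trachea, esophagus internal jugular vein",0,0
5,73,female,papillary,trachea,0,1
6,67,female,anaplastic,Trachea internal jugular vein,1,2
7,73,female,anaplastic,"trachea, esophagus",0,0
8,41,female,follicular,trachea,0,1
9,72,female,anaplastic,none,0,1
10,59,female,anaplastic,trachea,0,1
11,83,female,papillary,trachea,0,0
12,77,female,follicular,trachea,0,1
13,52,female,anaplastic,trachea,0,0
14,51,female,follicular,trachea,0,0
15,66,female,anaplastic,trachea,0,1
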