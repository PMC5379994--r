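marker,group,cells_total,cells_positive,foci_total,reference_group
PSPC1,GFP,813,598,5079,
PSPC1,GFP-IMPa2-FL,166,91,595,GFP-IMPa2-FL
PSPC1,GFP-IMPa2-dIBB,519,144,728,GFP-IMPa2-FL
PSPC1,GFP-IMPa2-ED,459,211,1461,GFP-IMPa2-FL
PSPC1,GFP-IMPa6-FL,431,285,2597,GFP-IMPa6-FL
PSPC1,GFP-IMPa6-dIBB,214,66,405,GFP-IMPa6-FL
SFPQ,GFP,566,460,4570,
SFPQ,GFP-IMPa2-FL,192,161,1529,GFP-IMPa2-FL
SFPQ,GFP-IMPa2-dIBB,301,174,1666,GFP-IMPa2-FL
SFPQ,GFP-IMPa2-ED,143,84,845,GFP-IMPa2-FL
SFPQ,GFP-IMPa4-FL,173,158,1787,GFP-IMPa4-FL
SFPQ,GFP-IMPa4-dIBB,299,180,1297,GFP-IMPa4-FL
SFPQ,GFP-IMPa6-FL,273,234,2123,GFP-IMPa6-FL
SFPQ,GFP-IMPa6-dIBB,311,128,933,GFP-IMPa6-FL
DsRed2-PSPC1,GFP,180,50,2508,
DsRed2-PSPC1,GFP-IMPa2-FL,228,117,3392,GFP-IMPa2-FL
DsRed2-PSPC1,GFP-IMPa2-dIBB,241,92,2147,GFP-IMPa2-FL
DsRed2-PSPC1,GFP-IMPa2-ED,446,195,6218,GFP-IMPa2-FL
DsRed2-PSPC1,GFP-IMPa4-FL,317,189,10853,GFP-IMPa4-FL
DsRed2-PSPC1,GFP-IMPa4-dIBB,386,143,4339,GFP-IMPa4-FL
DsRed2-PSPC1,GFP-IMPa6-FL,513,195,5473,GFP-IMPa6-FL
DsRed2-PSPC1,GFP-IMPa6-dIBB,219,87,3745,GFP-IMPa6-FL
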