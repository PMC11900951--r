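item_id,subscale,label
S1,symptoms,grinding or clicking in the hip
S2,symptoms,difficulty spreading legs wide apart
S3,symptoms,difficulty striding out when walking
S4,symptoms,stiffness after first wakening
S5,symptoms,stiffness later in the day
P1,pain,frequency of hip pain
P2,pain,pain straightening the hip fully
P3,pain,pain bending the hip fully
P4,pain,pain walking on a flat surface
P5,pain,pain going up or down stairs
P6,pain,pain at night while in bed
P7,pain,pain sitting or lying
P8,pain,pain standing upright
P9,pain,pain walking on a hard surface
P10,pain,pain walking on an uneven surface
A1,activities,descending stairs
A2,activities,ascending stairs
A3,activities,rising from sitting
A4,activities,standing
A5,activities,bending to the floor
A6,activities,walking on a flat surface
A7,activities,getting in or out of a car
A8,activities,going shopping
A9,activities,putting on socks or stockings
A10,activities,rising from bed
A11,activities,taking off socks or stockings
A12,activities,lying in bed
A13,activities,getting in or out of the bath
A14,activities,sitting
A15,activities,getting on or off the toilet
A16,activities,heavy domestic duties
A17,activities,light domestic duties
SP1,sport,squatting
SP2,sport,running
SP3,sport,twisting or pivoting on the loaded leg
SP4,sport,walking on an uneven surface
Q1,qol,awareness of hip problems
Q2,qol,lifestyle modification to avoid damaging activities
Q3,qol,being troubled by lack of confidence in the hip
Q4,qol,overall difficulty with the hip
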