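condition,trial,stimulus_id,opt1,opt2,opt3,opt4,correct_index
0,0,stim_12,stim_04,stim_12,stim_14,stim_11,1
0,1,stim_08,stim_06,stim_02,stim_04,stim_08,3
0,2,stim_01,stim_01,stim_03,stim_06,stim_02,0
0,3,stim_07,stim_03,stim_14,stim_07,stim_12,2
0,4,stim_15,stim_10,stim_11,stim_05,stim_15,3
0,5,stim_13,stim_13,stim_15,stim_04,stim_01,0
0,6,stim_16,stim_05,stim_10,stim_06,stim_16,3
0,7,stim_04,stim_08,stim_04,stim_13,stim_05,1
0,8,stim_11,stim_10,stim_11,stim_15,stim_12,1
0,9,stim_09,stim_16,stim_09,stim_04,stim_02,1
0,10,stim_06,stim_06,stim_13,stim_03,stim_05,0
0,11,stim_02,stim_05,stim_03,stim_02,stim_08,2
0,12,stim_03,stim_04,stim_12,stim_03,stim_09,2
0,13,stim_14,stim_04,stim_11,stim_16,stim_14,3
0,14,stim_10,stim_04,stim_05,stim_10,stim_07,2
0,15,stim_05,stim_05,stim_13,stim_15,stim_08,0
90,0,stim_03,stim_15,stim_14,stim_09,stim_03,3
90,1,stim_07,stim_07,stim_08,stim_16,stim_09,0
90,2,stim_01,stim_11,stim_06,stim_01,stim_02,2
90,3,stim_13,stim_05,stim_13,stim_16,stim_03,1
90,4,stim_14,stim_16,stim_01,stim_04,stim_14,3
90,5,stim_10,stim_09,stim_10,stim_16,stim_13,1
90,6,stim_12,stim_12,stim_02,stim_14,stim_04,0
90,7,stim_16,stim_02,stim_14,stim_07,stim_16,3
90,8,stim_09,stim_07,stim_13,stim_09,stim_04,2
90,9,stim_02,stim_16,stim_05,stim_09,stim_02,3
90,10,stim_15,stim_07,stim_15,stim_05,stim_04,1
90,11,stim_06,stim_01,stim_06,stim_02,stim_03,1
90,12,stim_11,stim_11,stim_05,stim_08,stim_03,0
90,13,stim_04,stim_13,stim_10,stim_04,stim_01,2
90,14,stim_08,stim_13,stim_14,stim_08,stim_01,2
90,15,stim_05,stim_05,stim_15,stim_11,stim_12,0
180,0,stim_13,stim_11,stim_09,stim_12,stim_13,3
180,1,stim_01,stim_15,stim_01,stim_06,stim_03,1
180,2,stim_16,stim_10,stim_12,stim_16,stim_03,2
180,3,stim_02,stim_02,stim_04,stim_05,stim_12,0
180,4,stim_12,stim_11,stim_14,stim_12,stim_06,2
180,5,stim_14,stim_12,stim_14,stim_01,stim_15,1
180,6,stim_15,stim_12,stim_05,stim_15,stim_08,2
180,7,stim_07,stim_07,stim_02,stim_15,stim_10,0
180,8,stim_06,stim_01,stim_08,stim_09,stim_06,3
180,9,stim_10,stim_12,stim_10,stim_16,stim_05,1
180,10,stim_05,stim_12,stim_11,stim_16,stim_05,3
180,11,stim_11,stim_14,stim_05,stim_15,stim_11,3
180,12,stim_03,stim_03,stim_01,stim_10,stim_15,0
180,13,stim_04,stim_04,stim_02,stim_10,stim_16,0
180,14,stim_09,stim_15,stim_01,stim_09,stim_08,2
180,15,stim_08,stim_03,stim_08,stim_06,stim_10,1
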