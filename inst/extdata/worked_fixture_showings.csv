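type_id,directional,attention,referent,mode,anchor
1,gaze_box,gaze_owner,2,alternation,0.00
2,gaze_box,move_owner,3,overlap,7.00
3,gaze_box,vocalize,2,alternation,14.00
4,move_box,gaze_owner,3,overlap,21.00
5,move_box,move_owner,2,alternation,28.00
6,move_box,vocalize,3,overlap,35.00
7,near_box,gaze_owner,2,alternation,42.00
8,near_box,move_owner,3,overlap,49.00
9,near_box,vocalize,2,alternation,56.00
10,jump_box,gaze_owner,3,overlap,63.00
11,jump_box,move_owner,2,alternation,70.00
12,jump_box,vocalize,3,overlap,77.00
13,open_box,gaze_owner,2,alternation,84.00
14,open_box,move_owner,3,overlap,91.00
15,open_box,vocalize,2,alternation,98.00
3,gaze_box,vocalize,1,alternation,105.00
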